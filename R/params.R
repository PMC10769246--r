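#' Acquisition parameters for a sequential-round FLASH-PAINT run
#'
#' Defaults follow typical exchange-style DNA-PAINT acquisitions: seven
#' sequential rounds of 30,000 frames at 25 ms exposure on a camera with an
#' effective pixel size of 108 nm. Blinking is discretised at frame
#' resolution as a two-state (dark/bright) renewal process; `eraser_residual`
#' is the fraction of a species' adapters that survive its erasure step and
#' can still generate signal in later rounds.
#'
#' @param n_rounds Number of sequential imaging rounds.
#' @param frames_per_round Frames acquired per round.
#' @param exposure_ms Exposure time per frame (ms); bookkeeping only, the
#'   kinetics are parameterised directly in frames.
#' @param mean_bright_frames Mean duration (frames, >= 1) of a binding event.
#' @param mean_dark_frames Mean interval (frames) between events at one
#'   active site.
#' @param photons_per_frame Expected photons collected per bright frame.
#' @param background_photons Expected background photons per pixel per frame.
#' @param psf_sigma Gaussian PSF sd (nm).
#' @param pixel_size Camera pixel size (nm).
#' @param eraser_residual Residual active fraction epsilon in [0, 1) after a
#'   species' eraser step; contamination compounds as epsilon^(r - s).
#'
#' @return An `imaging_params` list.
#' @export
imaging_params <- function(n_rounds = 7L,
                           frames_per_round = 30000L,
                           exposure_ms = 25,
                           mean_bright_frames = 3,
                           mean_dark_frames = 500,
                           photons_per_frame = 300,
                           background_photons = 5,
                           psf_sigma = 130,
                           pixel_size = 108,
                           eraser_residual = 0) {
  p <- list(n_rounds = as.integer(n_rounds),
            frames_per_round = as.integer(frames_per_round),
            exposure_ms = exposure_ms,
            mean_bright_frames = mean_bright_frames,
            mean_dark_frames = mean_dark_frames,
            photons_per_frame = photons_per_frame,
            background_photons = background_photons,
            psf_sigma = psf_sigma,
            pixel_size = pixel_size,
            eraser_residual = eraser_residual)
  rates <- c("frames_per_round", "mean_bright_frames", "mean_dark_frames",
             "photons_per_frame", "psf_sigma", "pixel_size")
  for (nm in rates) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop(nm, " must be > 0")
  if (p$mean_bright_frames < 1) stop("mean_bright_frames must be >= 1")
  if (p$background_photons < 0) stop("background_photons must be >= 0")
  if (p$n_rounds < 1) stop("n_rounds must be >= 1")
  if (p$eraser_residual < 0 || p$eraser_residual >= 1)
    stop("eraser_residual must be in [0, 1)")
  structure(p, class = "imaging_params")
}
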