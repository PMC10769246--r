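#' List-mode localizations from blink events
#'
#' Shortcuts the camera: each blink event yields one localization at the
#' site's true position, displaced by the stage drift at the event's middle
#' frame and by isotropic Gaussian localization error with per-axis sd
#' `psf_sigma / sqrt(total_photons)`. Events with zero photons are dropped
#' (counted in attribute `n_dropped_zero_photon`).
#'
#' @param events A `blink_events` data.frame.
#' @param sites The `binding_site_set` the events refer to.
#' @param drift A `drift_trajectory` covering all referenced global frames.
#' @param params The `imaging_params` used for the simulation.
#' @param seed Integer seed.
#'
#' @return A `localization_table` (see [as_localization_table()]): columns
#'   `frame` (global, 0-based), `round`, `x`, `y` (nm), `photons`,
#'   `sigma_psf_fit`, `background`, `loc_precision` (nm), `species`
#'   (ground-truth 0-based id), `site_index`. Sorted by (round, frame).
#' @export
events_to_localizations <- function(events, sites, drift, params, seed = 1L) {
  stopifnot(inherits(params, "imaging_params"))
  set.seed(as.integer(seed))
  keep <- events$total_photons > 0
  n_drop <- sum(!keep)
  if (n_drop > 0)
    warning(n_drop, " zero-photon event(s) dropped")
  ev <- events[keep, , drop = FALSE]
  mid <- ev$round * params$frames_per_round + ev$start_frame +
    ev$n_frames %/% 2L
  if (nrow(ev) && (max(mid) + 1L) > nrow(drift))
    stop("drift trajectory does not cover all referenced frames")
  sigma_loc <- params$psf_sigma / sqrt(ev$total_photons)
  n <- nrow(ev)
  tab <- data.frame(
    frame = ev$round * params$frames_per_round + ev$start_frame,
    round = ev$round,
    x = sites$x[ev$site_index] + drift$dx[mid + 1L] +
      stats::rnorm(n, 0, sigma_loc),
    y = sites$y[ev$site_index] + drift$dy[mid + 1L] +
      stats::rnorm(n, 0, sigma_loc),
    photons = ev$total_photons,
    sigma_psf_fit = rep.int(params$psf_sigma, n),
    background = rep.int(NA_real_, n),
    loc_precision = sigma_loc,
    species = ev$species_id,
    site_index = ev$site_index)
  tab <- as_localization_table(tab, pixel_size = params$pixel_size,
                               frames_per_round = params$frames_per_round)
  attr(tab, "n_dropped_zero_photon") <- n_drop
  tab
}

#' Construct / validate a localization table
#'
#' The central record of the pipeline: one row per localization with
#' coordinates in nm (image convention: origin at the field's top-left,
#' x right, y down), 0-based global frame and round indices. The
#' `drift_corrected` and `rounds_aligned` attributes track post-processing
#' state; `species` carries ground truth for synthetic data and may be `NA`
#' for real data.
#'
#' @param df A data.frame with at least `frame`, `round`, `x`, `y`,
#'   `photons`, `loc_precision`.
#' @param pixel_size Camera pixel size (nm), kept as an attribute.
#' @param frames_per_round Frames per round, kept as an attribute.
#' @param drift_corrected,rounds_aligned Post-processing flags.
#' @return The validated table, class `localization_table`.
#' @export
as_localization_table <- function(df, pixel_size = NA_real_,
                                  frames_per_round = NA_integer_,
                                  drift_corrected = FALSE,
                                  rounds_aligned = FALSE) {
  need <- c("frame", "round", "x", "y", "photons", "loc_precision")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (!"sigma_psf_fit" %in% names(df))
    df$sigma_psf_fit <- rep(NA_real_, nrow(df))
  if (!"background" %in% names(df))
    df$background <- rep(NA_real_, nrow(df))
  if (!"species" %in% names(df))
    df$species <- rep(NA_integer_, nrow(df))
  with(df, {
    if (any(!is.finite(x)) || any(!is.finite(y)))
      stop("x, y must be finite")
    if (any(photons <= 0)) stop("photons must be > 0")
    if (any(loc_precision <= 0)) stop("loc_precision must be > 0")
  })
  df <- df[order(df$round, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            pixel_size = pixel_size,
            frames_per_round = frames_per_round,
            drift_corrected = drift_corrected,
            rounds_aligned = rounds_aligned,
            class = c("localization_table", "data.frame"))
}

loc_attrs <- function(tab) {
  attributes(tab)[c("pixel_size", "frames_per_round",
                    "drift_corrected", "rounds_aligned")]
}

restore_loc_attrs <- function(tab, at) {
  as_localization_table(tab,
                        pixel_size = at$pixel_size,
                        frames_per_round = at$frames_per_round,
                        drift_corrected = isTRUE(at$drift_corrected),
                        rounds_aligned = isTRUE(at$rounds_aligned))
}
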