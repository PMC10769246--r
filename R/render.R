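#' Render blink events into synthetic camera frames
#'
#' Frame-mode output: for every bright frame of every event an integrated 2-D
#' Gaussian (sd `psf_sigma`) centred on the drifted emitter position
#' contributes its expected photons to the frame's intensity map; the
#' recorded pixel value is Poisson-distributed around the accumulated
#' expectation plus the uniform background. The per-frame expected photon
#' count of an event is `total_photons / n_frames`, so photon bookkeeping is
#' consistent with list mode.
#'
#' @param events A `blink_events` data.frame.
#' @param sites The matching `binding_site_set`.
#' @param drift A `drift_trajectory` covering all frames.
#' @param params An `imaging_params` (pixel size, PSF, background).
#' @param field_px Length-2 integer: frame size in pixels (nx, ny). The
#'   field `field_px * pixel_size` must cover the site coordinates.
#' @param seed Integer seed.
#'
#' @return A `frame_stack`: list with `frames` (integer array
#'   ny x nx x n_frames), and `meta` (list: pixel_size, psf_sigma,
#'   background, n_rounds, frames_per_round, round_ranges — 0-based
#'   inclusive global frame ranges per round — and `n_clipped`, the count of
#'   emitter-frames falling entirely outside the field).
#' @export
render_movie <- function(events, sites, drift, params, field_px, seed = 1L) {
  stopifnot(inherits(params, "imaging_params"), length(field_px) == 2)
  set.seed(as.integer(seed))
  nx <- as.integer(field_px[1]); ny <- as.integer(field_px[2])
  a <- params$pixel_size
  if (nrow(sites) && (max(sites$x) > nx * a || max(sites$y) > ny * a))
    stop("field_px * pixel_size does not cover the site coordinates")
  n_total <- params$n_rounds * params$frames_per_round
  if (nrow(drift) < n_total) stop("drift trajectory too short")
  half <- ceiling(4 * params$psf_sigma / a)
  # expand events to one row per bright frame (global index)
  reps <- events$n_frames
  gstart <- events$round * params$frames_per_round + events$start_frame
  em_frame <- rep(gstart, reps) + sequence(reps) - 1L
  em_rate <- rep(events$total_photons / pmax(events$n_frames, 1L), reps)
  em_site <- rep(events$site_index, reps)
  ord <- order(em_frame)
  em_frame <- em_frame[ord]; em_rate <- em_rate[ord]; em_site <- em_site[ord]
  frames <- array(0L, dim = c(ny, nx, n_total))
  n_clipped <- 0L
  ptr <- 1L
  n_em <- length(em_frame)
  for (f in seq_len(n_total) - 1L) {
    lam <- matrix(params$background_photons, ny, nx)
    while (ptr <= n_em && em_frame[ptr] == f) {
      sx <- sites$x[em_site[ptr]] + drift$dx[f + 1L]
      sy <- sites$y[em_site[ptr]] + drift$dy[f + 1L]
      cx <- floor(sx / a) + 1; cy <- floor(sy / a) + 1
      xr <- max(1, cx - half):min(nx, cx + half)
      yr <- max(1, cy - half):min(ny, cy + half)
      if (cx + half < 1 || cx - half > nx || cy + half < 1 || cy - half > ny) {
        n_clipped <- n_clipped + 1L
      } else {
        wx <- stats::pnorm((xr * a - sx) / params$psf_sigma) -
          stats::pnorm(((xr - 1) * a - sx) / params$psf_sigma)
        wy <- stats::pnorm((yr * a - sy) / params$psf_sigma) -
          stats::pnorm(((yr - 1) * a - sy) / params$psf_sigma)
        lam[yr, xr] <- lam[yr, xr] + em_rate[ptr] * outer(wy, wx)
      }
      ptr <- ptr + 1L
    }
    frames[, , f + 1L] <- pmin(stats::rpois(ny * nx, lam), 65535L)
  }
  meta <- list(pixel_size = a,
               psf_sigma = params$psf_sigma,
               background = params$background_photons,
               n_rounds = params$n_rounds,
               frames_per_round = params$frames_per_round,
               round_ranges = lapply(seq_len(params$n_rounds) - 1L, function(r)
                 c(r * params$frames_per_round,
                   (r + 1L) * params$frames_per_round - 1L)),
               n_clipped = n_clipped)
  structure(list(frames = frames, meta = meta), class = "frame_stack")
}

#' Write a frame stack as multi-page TIFF with a YAML sidecar
#'
#' Frames are stored 16-bit; the sidecar records pixel size, round layout and
#' rendering metadata so the stack is self-describing.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path; the sidecar is written at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- stack$meta
  meta$n_frames <- dim(fr)[3]
  meta$dim_px <- c(dim(fr)[2], dim(fr)[1])
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path TIFF path with `<path>.yaml` sidecar alongside.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta$n_frames) && length(pages) != meta$n_frames)
    stop("sidecar/stack frame-count mismatch: sidecar says ", meta$n_frames,
         ", TIFF has ", length(pages))
  fr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    fr[, , k] <- as.integer(round(pages[[k]] * 65535))
  meta$round_ranges <- lapply(meta$round_ranges, as.numeric)
  structure(list(frames = fr, meta = meta), class = "frame_stack")
}
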