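#' Simulate a stage-drift trajectory
#'
#' Cumulative sum of i.i.d. Gaussian per-frame steps plus a linear component,
#' anchored so that frame 0 has zero displacement.
#'
#' @param n_frames_total Total number of frames (all rounds).
#' @param step_sigma Random-walk step sd (nm per frame, >= 0).
#' @param linear_velocity Length-2 numeric, deterministic drift velocity
#'   (nm per frame) in x and y.
#' @param seed Integer seed.
#'
#' @return A `drift_trajectory` data.frame with columns `dx`, `dy` (nm),
#'   one row per global frame.
#' @export
simulate_drift <- function(n_frames_total, step_sigma = 0,
                           linear_velocity = c(0, 0), seed = 1L) {
  if (step_sigma < 0) stop("step_sigma must be >= 0")
  stopifnot(n_frames_total >= 1, length(linear_velocity) == 2)
  set.seed(as.integer(seed))
  n <- as.integer(n_frames_total)
  step <- function(v) c(0, cumsum(stats::rnorm(n - 1L, v, step_sigma)))
  structure(data.frame(dx = step(linear_velocity[1]),
                       dy = step(linear_velocity[2])),
            class = c("drift_trajectory", "data.frame"))
}
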