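#' Simulate sequential-round blinking kinetics
#'
#' In round `r` (0-based) the active sites are all sites of species `r` plus,
#' for every earlier species `s < r`, each of its sites independently with
#' probability `eraser_residual^(r - s)` (imperfect erasure compounding
#' geometrically). Species with `s > r` have not yet received their adapter
#' and are never active. Each active site emits binding events as an
#' alternating renewal process discretised at frame resolution: dark gaps
#' are geometric with mean `mean_dark_frames` (support 0, 1, ...), bright
#' dwells geometric with mean `mean_bright_frames` (support 1, 2, ...).
#' Event photon counts are Poisson with mean
#' `n_frames * photons_per_frame`.
#'
#' @param sites A `binding_site_set`.
#' @param params An `imaging_params`; `n_rounds` must not exceed the number
#'   of species in the panel.
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A `blink_events` data.frame: `site_index` (1-based row into
#'   `sites`), `species_id`, `round` (0-based), `start_frame` (0-based,
#'   within round), `n_frames`, `total_photons`, ordered by
#'   (round, start_frame, site_index).
#' @export
simulate_rounds <- function(sites, params, seed = 1L) {
  stopifnot(inherits(params, "imaging_params"))
  eps <- params$eraser_residual
  if (eps >= 1) stop("eraser_residual must be < 1")
  n_species <- if (nrow(sites)) max(sites$species_id) + 1L else 0L
  if (any(sites$species_id >= params$n_rounds))
    stop("every site's species_id must be < n_rounds ",
         "(round r images species r)")
  if (params$n_rounds > n_species)
    stop("n_rounds (", params$n_rounds, ") exceeds the number of species (",
         n_species, ") in the panel")
  set.seed(as.integer(seed))
  F <- params$frames_per_round
  out <- vector("list", params$n_rounds)
  for (r in seq_len(params$n_rounds) - 1L) {
    own <- which(sites$species_id == r)
    carry <- integer(0)
    if (eps > 0 && r > 0) {
      for (s in 0:(r - 1L)) {
        idx <- which(sites$species_id == s)
        if (length(idx))
          carry <- c(carry, idx[stats::runif(length(idx)) < eps^(r - s)])
      }
    }
    active <- c(own, carry)
    if (!length(active)) next
    ev <- blink_trains(length(active), F,
                       params$mean_dark_frames, params$mean_bright_frames)
    if (!nrow(ev)) next
    site_idx <- active[ev$unit]
    out[[r + 1L]] <- data.frame(
      site_index = site_idx,
      species_id = sites$species_id[site_idx],
      round = rep.int(r, nrow(ev)),
      start_frame = ev$start,
      n_frames = ev$len,
      total_photons = stats::rpois(nrow(ev),
                                   ev$len * params$photons_per_frame))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(site_index = integer(0), species_id = integer(0),
                      round = integer(0), start_frame = integer(0),
                      n_frames = integer(0), total_photons = integer(0))
  out <- out[order(out$round, out$start_frame, out$site_index), ]
  rownames(out) <- NULL
  structure(out, class = c("blink_events", "data.frame"))
}

# Alternating dark/bright renewal trains for n units over `frames` frames.
# Cycles are drawn in batches; units whose train has not yet covered the
# acquisition get further batches. Returns 0-based start frames and bright
# lengths truncated at the round end.
blink_trains <- function(n, frames, mean_dark, mean_bright) {
  p_dark <- 1 / (mean_dark + 1)     # rgeom mean (1-p)/p = mean_dark
  p_bright <- 1 / mean_bright       # 1 + rgeom mean = mean_bright
  exp_cycle <- mean_dark + mean_bright
  unit <- integer(0); start <- integer(0); len <- integer(0)
  t_now <- rep.int(0, n)            # next free frame per unit
  alive <- seq_len(n)
  while (length(alive)) {
    k <- max(4L, ceiling(1.5 * frames / exp_cycle))
    na <- length(alive)
    dark <- matrix(stats::rgeom(na * k, p_dark), na, k)
    bright <- matrix(stats::rgeom(na * k, p_bright) + 1L, na, k)
    # event j starts after cumulative prior cycles + its dark gap
    cyc <- dark + bright
    ends <- t(apply(cyc, 1L, cumsum)) + t_now[alive]
    starts <- ends - bright
    ok <- starts < frames
    if (any(ok)) {
      u <- rep(alive, k)[ok]
      s <- starts[ok]
      b <- pmin(bright[ok], frames - s)
      unit <- c(unit, u); start <- c(start, s); len <- c(len, b)
    }
    t_now[alive] <- ends[, k]
    alive <- alive[ends[, k] < frames]
  }
  data.frame(unit = unit, start = as.integer(start), len = as.integer(len))
}
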