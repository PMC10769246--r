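# Independent oracles used across the suite. These deliberately re-derive
# quantities with straightforward code (brute-force scans, direct Monte
# Carlo) rather than calling the implementation under test.

# exhaustive O(n^2) cross-distance scan; nn = per-query minimum
brute_nn <- function(A, B, self = FALSE) {
  D <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2)
  if (self) diag(D) <- Inf
  apply(D, 1, min)
}

brute_pairs_within <- function(A, B, rmax, self = FALSE) {
  D <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2)
  if (self) diag(D) <- Inf
  D[D <= rmax]
}

# number of binding events started by one site over `frames` frames under
# alternating geometric dark (mean m_dark, support 0..) / bright (mean
# m_bright, support 1..) kinetics; direct per-site simulation, vectorised
# over a pool of sites via cumulative cycle sums
renewal_counts <- function(n, frames, m_dark, m_bright) {
  p_d <- 1 / (m_dark + 1)
  p_b <- 1 / m_bright
  counts <- integer(n)
  todo <- seq_len(n)
  t_now <- numeric(n)
  while (length(todo)) {
    k <- max(4L, ceiling(2 * frames / (m_dark + m_bright)))
    nd <- length(todo)
    dark <- matrix(stats::rgeom(nd * k, p_d), nd, k)
    bright <- matrix(stats::rgeom(nd * k, p_b) + 1, nd, k)
    ends <- t(apply(dark + bright, 1, cumsum)) + t_now[todo]
    starts <- ends - bright
    counts[todo] <- counts[todo] + rowSums(starts < frames)
    t_now[todo] <- ends[, k]
    todo <- todo[ends[, k] < frames]
  }
  counts
}

# Monte-Carlo oracle for the two-layer nearest-neighbour median: draws
# independent realisations of one species-A localization against a fresh
# species-B point process (sites Poisson on a parallel line `delta` away,
# per-site event counts from the same renewal kinetics, per-event photon
# draws and localization noise psf/sqrt(photons)), and returns the median
# of the nn distances retained under the cutoff. `win` truncates the site
# line to +-win nm around the query, wide enough that the nearest event is
# essentially always inside.
two_layer_nn_oracle <- function(ndraw, delta, density_per_nm, frames,
                                m_dark, m_bright, photon_mean,
                                psf = 130, rmax = 500, win = 250,
                                seed = 1L, chunk = 5000L) {
  set.seed(seed)
  pool <- renewal_counts(200000L, frames, m_dark, m_bright)
  mins <- numeric(ndraw)
  done <- 0L
  while (done < ndraw) {
    m <- min(chunk, ndraw - done)
    qp <- pmax(stats::rpois(m, photon_mean), 1)
    qx <- stats::rnorm(m, 0, psf / sqrt(qp))
    qy <- stats::rnorm(m, 0, psf / sqrt(qp))
    nsites <- stats::rpois(m, density_per_nm * 2 * win)
    draw_of_site <- rep(seq_len(m), nsites)
    sx <- stats::runif(sum(nsites), -win, win)
    nev <- sample(pool, sum(nsites), replace = TRUE)
    draw_of_ev <- rep(draw_of_site, nev)
    ex <- rep(sx, nev)
    np <- length(ex)
    ep <- pmax(stats::rpois(np, photon_mean), 1)
    ex <- ex + stats::rnorm(np, 0, psf / sqrt(ep))
    ey <- delta + stats::rnorm(np, 0, psf / sqrt(ep))
    d <- sqrt((ex - qx[draw_of_ev])^2 + (ey - qy[draw_of_ev])^2)
    o <- order(draw_of_ev, d)
    first <- !duplicated(draw_of_ev[o])
    dmin <- rep(Inf, m)
    dmin[draw_of_ev[o][first]] <- d[o][first]
    mins[done + seq_len(m)] <- dmin
    done <- done + m
  }
  stats::median(mins[mins <= rmax])
}

# small list-mode simulation helper used by several tests
sim_list_mode <- function(geom_cfg, imaging_args, seed,
                          labeling_efficiency = 1, linkage_sigma = 0,
                          drift = NULL) {
  g <- build_geometry(geom_cfg)
  s <- place_binding_sites(g, labeling_efficiency, linkage_sigma,
                           seed = seed)
  p <- do.call(imaging_params, imaging_args)
  ev <- simulate_rounds(s, p, seed = seed + 1L)
  if (is.null(drift))
    drift <- simulate_drift(p$n_rounds * p$frames_per_round, 0, c(0, 0),
                            seed = seed + 2L)
  tab <- events_to_localizations(ev, s, drift, p, seed = seed + 3L)
  list(geometry = g, sites = s, params = p, events = ev, drift = drift,
       table = tab)
}
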