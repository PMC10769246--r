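#' Detect candidate spots in one frame
#'
#' The frame is smoothed with a 3x3 box filter; pixels exceeding
#' `median + threshold_k * MAD` of the smoothed frame and not smaller than
#' any 8-neighbour are candidates. Candidates closer than `min_sep_px`
#' pixels (Euclidean) are merged keeping the brighter one; ties go to the
#' smaller row, then column index. The one-pixel border is excluded.
#'
#' @param frame Non-negative 2-D intensity matrix (rows = y, cols = x).
#' @param threshold_k Robust-sd multiplier above the median.
#' @param min_sep_px Minimal separation between kept candidates (pixels).
#' @return A data.frame with 1-based `row`, `col` pixel indices and the
#'   smoothed `intensity`, ordered brightest first.
#' @export
detect_candidates <- function(frame, threshold_k = 5, min_sep_px = 4) {
  stopifnot(is.matrix(frame), all(frame >= 0))
  ny <- nrow(frame); nx <- ncol(frame)
  empty <- data.frame(row = integer(0), col = integer(0),
                      intensity = numeric(0))
  if (ny < 3 || nx < 3) return(empty)
  sm <- box3(frame)
  thr <- stats::median(sm) + threshold_k * stats::mad(sm)
  core <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= sm[2:(ny - 1) + di, 2:(nx - 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     intensity = sm[cbind(idx[, 1] + 1L, idx[, 2] + 1L)])
  cand <- cand[order(-cand$intensity, cand$row, cand$col), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- all(d2 >= min_sep_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

box3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(0, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- m
  s <- matrix(0, ny, nx)
  for (di in 0:2) for (dj in 0:2)
    s <- s + p[di + 1:ny, dj + 1:nx]
  s / 9
}

#' Fit one spot by maximum likelihood
#'
#' Fits an integrated symmetric 2-D Gaussian plus constant background to a
#' square ROI under a Poisson noise model (L-BFGS-B, iteration budget 50).
#' The expected count in pixel (i, j) is
#' `N * dPhi_x(j) * dPhi_y(i) + b`, with `dPhi` the Gaussian mass integrated
#' over the pixel. The reported localization precision uses the standard
#' closed form
#' `sqrt((sigma^2 + a^2/12)/N * (16/9 + 8*pi*sigma^2*b/(N*a^2)))`
#' with the fitted photon count `N`, background `b` (photons/pixel), PSF sd
#' `sigma` and pixel size `a`. Non-convergence falls back to the
#' background-subtracted centroid with `converged = FALSE`.
#'
#' @param roi Square intensity patch, side `2m + 1` with `m >= 3`.
#' @param pixel_size Pixel size `a` (nm).
#' @param psf_sigma_init Initial / nominal PSF sd (nm); the fitted sd is
#'   constrained to `[0.5, 3]` times this value.
#' @return A `spot_fit` list: `x`, `y` (nm from the ROI top-left corner),
#'   `photons`, `background`, `sigma` (nm), `loc_precision` (nm),
#'   `converged`.
#' @export
fit_spot <- function(roi, pixel_size, psf_sigma_init) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi))
  m <- (nrow(roi) - 1) / 2
  if (m < 3) stop("ROI half-size must be >= 3")
  a <- pixel_size
  npx <- nrow(roi)
  if (all(roi == 0))
    return(spot_fit(npx * a / 2, npx * a / 2, 0, 0, psf_sigma_init, a, FALSE))
  edges <- a * (0:npx)
  tot <- sum(roi)
  b0 <- max(min(roi), 1e-6)
  n0 <- max(tot - b0 * npx^2, 1)
  w <- pmax(roi - b0, 0)
  cx0 <- sum(t(w) * (edges[-1] - a / 2)) / max(sum(w), 1e-12)
  cy0 <- sum(w * (edges[-1] - a / 2)) / max(sum(w), 1e-12)
  nll <- function(th) {
    dpx <- diff(stats::pnorm((edges - th[1]) / th[5]))
    dpy <- diff(stats::pnorm((edges - th[2]) / th[5]))
    lam <- th[3] * outer(dpy, dpx) + th[4]
    lam <- pmax(lam, 1e-12)
    sum(lam - roi * log(lam))
  }
  gr <- function(th) {
    s <- th[5]
    ux <- (edges - th[1]) / s
    uy <- (edges - th[2]) / s
    dpx <- diff(stats::pnorm(ux)); dpy <- diff(stats::pnorm(uy))
    phx <- stats::dnorm(ux); phy <- stats::dnorm(uy)
    lam <- pmax(th[3] * outer(dpy, dpx) + th[4], 1e-12)
    w <- 1 - roi / lam                       # d(nll)/d(lambda)
    dox_dx <- -diff(phx) / s                 # d dpx / dx
    doy_dy <- -diff(phy) / s
    dox_ds <- -diff(ux * phx) / s            # d dpx / ds
    doy_ds <- -diff(uy * phy) / s
    c(th[3] * sum(w * outer(dpy, dox_dx)),
      th[3] * sum(w * outer(doy_dy, dpx)),
      sum(w * outer(dpy, dpx)),
      sum(w),
      th[3] * sum(w * (outer(dpy, dox_ds) + outer(doy_ds, dpx))))
  }
  fit <- try(stats::optim(
    c(cx0, cy0, n0, b0, psf_sigma_init), nll, gr, method = "L-BFGS-B",
    lower = c(0, 0, 1e-3, 1e-9, 0.5 * psf_sigma_init),
    upper = c(npx * a, npx * a, Inf, Inf, 3 * psf_sigma_init),
    control = list(maxit = 50L, factr = 1e7)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0)
    return(spot_fit(cx0, cy0, n0, b0, psf_sigma_init, a, FALSE))
  th <- fit$par
  spot_fit(th[1], th[2], th[3], th[4], th[5], a, TRUE)
}

spot_fit <- function(x, y, photons, background, sigma, a, converged) {
  lp <- if (photons > 0)
    sqrt((sigma^2 + a^2 / 12) / photons *
           (16 / 9 + 8 * pi * sigma^2 * background / (photons * a^2)))
  else NA_real_
  structure(list(x = x, y = y, photons = photons, background = background,
                 sigma = sigma, loc_precision = lp, converged = converged),
            class = "spot_fit")
}

#' Localize a rendered frame stack
#'
#' Runs candidate detection and spot fitting on every frame, assigns each
#' localization its imaging round from the sidecar frame ranges, and drops
#' (counting) fits that do not converge or whose ROI leaves the frame.
#'
#' @param stack A `frame_stack` (see [render_movie()] / [read_frame_stack()]).
#' @param threshold_k Detection threshold multiplier.
#' @param roi_half ROI half-size in pixels; default
#'   `ceil(2 * psf_sigma / pixel_size) + 1`.
#' @return A `localization_table` in nm, sorted by (round, frame), with
#'   attributes `n_dropped_fits` and `n_edge_skipped`.
#' @export
localize_movie <- function(stack, threshold_k = 5, roi_half = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  meta <- stack$meta
  a <- meta$pixel_size
  sig <- meta$psf_sigma
  m <- roi_half %||% (ceiling(2 * sig / a) + 1)
  n_frames <- dim(stack$frames)[3]
  ranges <- meta$round_ranges
  round_of <- integer(n_frames)
  for (r in seq_along(ranges))
    round_of[(ranges[[r]][1]:ranges[[r]][2]) + 1L] <- r - 1L
  min_sep <- 2 * ceiling(sig / a)
  recs <- vector("list", n_frames)
  n_drop <- 0L; n_edge <- 0L
  ny <- dim(stack$frames)[1]; nx <- dim(stack$frames)[2]
  for (f in seq_len(n_frames)) {
    fr <- stack$frames[, , f]
    cand <- detect_candidates(fr, threshold_k, min_sep)
    if (!nrow(cand)) next
    rows <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r0 <- cand$row[i] - m; r1 <- cand$row[i] + m
      c0 <- cand$col[i] - m; c1 <- cand$col[i] + m
      if (r0 < 1 || c0 < 1 || r1 > ny || c1 > nx) {
        n_edge <- n_edge + 1L
        next
      }
      ft <- fit_spot(fr[r0:r1, c0:c1], a, sig)
      if (!ft$converged) {
        n_drop <- n_drop + 1L
        next
      }
      rows[[i]] <- data.frame(
        frame = f - 1L, round = round_of[f],
        x = (c0 - 1) * a + ft$x, y = (r0 - 1) * a + ft$y,
        photons = ft$photons, sigma_psf_fit = ft$sigma,
        background = ft$background, loc_precision = ft$loc_precision)
    }
    recs[[f]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, recs)
  if (is.null(tab))
    tab <- data.frame(frame = integer(0), round = integer(0),
                      x = numeric(0), y = numeric(0), photons = numeric(0),
                      sigma_psf_fit = numeric(0), background = numeric(0),
                      loc_precision = numeric(0))
  tab <- as_localization_table(tab, pixel_size = a,
                               frames_per_round = meta$frames_per_round)
  attr(tab, "n_dropped_fits") <- n_drop
  attr(tab, "n_edge_skipped") <- n_edge
  tab
}

#' Merge per-frame localizations of one binding event
#'
#' A binding event spanning several frames yields several localizations;
#' left unmerged they would weight the proximity medians by event length.
#' Localizations of the same round are chained when they fall within
#' `max_dist` of the chain's running position in consecutive frames,
#' allowing up to `max_gap` dark frames. Chains collapse to their
#' inverse-variance weighted mean; photons are summed and the combined
#' precision is `1 / sqrt(sum(1 / p_i^2))`. Processing order (frame, then
#' record index) and nearest-chain assignment make the result deterministic.
#'
#' @param table A `localization_table` sorted by (round, frame).
#' @param max_gap Maximum dark frames inside one chain.
#' @param max_dist Maximum distance (nm) to the chain position.
#' @return A merged `localization_table`; attribute `n_merged_from` gives
#'   the input record count.
#' @export
link_blinks <- function(table, max_gap = 1L, max_dist = 100) {
  stopifnot(inherits(table, "localization_table"))
  at <- loc_attrs(table)
  df <- as.data.frame(table)
  out <- vector("list", length(unique(df$round)))
  oi <- 0L
  for (r in sort(unique(df$round))) {
    d <- df[df$round == r, , drop = FALSE]
    n <- nrow(d)
    w <- 1 / d$loc_precision^2
    # chain accumulators
    ch_last <- integer(0); ch_first <- integer(0)
    ch_wx <- ch_wy <- ch_w <- ch_ph <- numeric(0)
    ch_id_of <- integer(n)
    for (i in seq_len(n)) {
      f <- d$frame[i]
      elig <- which(ch_last < f & ch_last >= f - (max_gap + 1L))
      hit <- 0L
      if (length(elig)) {
        dx <- ch_wx[elig] / ch_w[elig] - d$x[i]
        dy <- ch_wy[elig] / ch_w[elig] - d$y[i]
        d2 <- dx^2 + dy^2
        j <- which.min(d2)           # ties: earliest chain
        if (d2[j] <= max_dist^2) hit <- elig[j]
      }
      if (hit) {
        ch_last[hit] <- f
        ch_wx[hit] <- ch_wx[hit] + w[i] * d$x[i]
        ch_wy[hit] <- ch_wy[hit] + w[i] * d$y[i]
        ch_w[hit] <- ch_w[hit] + w[i]
        ch_ph[hit] <- ch_ph[hit] + d$photons[i]
        ch_id_of[i] <- hit
      } else {
        ch_last <- c(ch_last, f); ch_first <- c(ch_first, i)
        ch_wx <- c(ch_wx, w[i] * d$x[i]); ch_wy <- c(ch_wy, w[i] * d$y[i])
        ch_w <- c(ch_w, w[i]); ch_ph <- c(ch_ph, d$photons[i])
        ch_id_of[i] <- length(ch_last)
      }
    }
    first <- d[ch_first, , drop = FALSE]
    first$x <- ch_wx / ch_w
    first$y <- ch_wy / ch_w
    first$photons <- ch_ph
    first$loc_precision <- 1 / sqrt(ch_w)
    oi <- oi + 1L
    out[[oi]] <- first
  }
  merged <- do.call(rbind, out[seq_len(oi)])
  merged <- restore_loc_attrs(merged, at)
  attr(merged, "n_merged_from") <- nrow(df)
  merged
}
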