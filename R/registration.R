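#' Render a localization table as a 2-D histogram image
#'
#' Bins (x, y) at `bin_size` nm over a fixed extent, optionally blurring with
#' a Gaussian kernel. Before blurring the image mass equals the number of
#' rendered localizations; blurring conserves mass away from the border.
#'
#' @param table A `localization_table` (or data.frame with `x`, `y`).
#' @param bin_size Bin edge length (nm, > 0).
#' @param blur_sigma Gaussian blur sd (nm); 0 disables blurring.
#' @param extent Length-4 numeric `c(xmin, xmax, ymin, ymax)` nm; defaults
#'   to the data range padded by one bin.
#' @return A `rendered_image`: list with `pixels` (matrix, rows = y),
#'   `bin_size`, `origin` (xmin, ymin), `n_rendered`.
#' @export
render_histogram <- function(table, bin_size = 5, blur_sigma = 0,
                             extent = NULL) {
  stopifnot(bin_size > 0)
  x <- table$x; y <- table$y
  if (is.null(extent)) {
    if (length(x) == 0) extent <- c(0, bin_size, 0, bin_size)
    else extent <- c(min(x) - bin_size, max(x) + bin_size,
                     min(y) - bin_size, max(y) + bin_size)
  }
  nx <- max(1L, ceiling((extent[2] - extent[1]) / bin_size))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / bin_size))
  img <- matrix(0, ny, nx)
  if (length(x)) {
    ix <- floor((x - extent[1]) / bin_size) + 1L
    iy <- floor((y - extent[3]) / bin_size) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    counts <- table(factor((ix[ok] - 1L) * ny + iy[ok],
                           levels = seq_len(nx * ny)))
    img[] <- as.numeric(counts)
  } else ok <- logical(0)
  if (blur_sigma > 0) img <- gauss_blur(img, blur_sigma / bin_size)
  structure(list(pixels = img, bin_size = bin_size,
                 origin = c(extent[1], extent[3]),
                 n_rendered = sum(ok)),
            class = "rendered_image")
}

# separable Gaussian blur, zero-padded (linear, not circular)
gauss_blur <- function(img, sigma_bins) {
  if (sigma_bins <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(-h:h, 0, sigma_bins)
  k <- k / sum(k)
  conv1 <- function(m) {   # convolve columns of m with k, zero padding
    ny <- nrow(m)
    p <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
    out <- matrix(0, ny, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * p[(j - 1) + seq_len(ny), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# circular cross-correlation shift of image A relative to B with 3-point
# quadratic sub-bin interpolation; returns c(dx, dy) in bins such that
# A approx B shifted by (dx, dy), or NULL for a degenerate (flat) surface
xcorr_shift <- function(A, B) {
  FA <- stats::fft(A); FB <- stats::fft(B)
  cc <- Re(stats::fft(FA * Conj(FB), inverse = TRUE))
  if (max(cc) - min(cc) <= .Machine$double.eps * max(abs(cc), 1))
    return(NULL)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ny <- nrow(cc); nx <- ncol(cc)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  sub <- function(c0, cm, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else 0.5 * (cm - cp) / den
  }
  dyi <- pk[1]; dxi <- pk[2]
  dy <- (dyi - 1) + sub(cc[dyi, dxi],
                        cc[wrap(dyi - 1, ny), dxi],
                        cc[wrap(dyi + 1, ny), dxi])
  dx <- (dxi - 1) + sub(cc[dyi, dxi],
                        cc[dyi, wrap(dxi - 1, nx)],
                        cc[dyi, wrap(dxi + 1, nx)])
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dx = dx, dy = dy)
}

#' Estimate drift by redundant cross-correlation (RCC)
#'
#' Splits each round's frames into `n_segments` equal temporal blocks,
#' renders each block as a blurred histogram, measures all pairwise block
#' shifts by cross-correlation with sub-bin quadratic peak interpolation,
#' and solves the overdetermined pairwise system by least squares for the
#' per-block displacements (first block anchored at zero). Block
#' displacements are interpolated linearly (and extrapolated at the round
#' ends) to per-frame drift.
#'
#' RCC is blind to a constant offset per round. With `chain_rounds = TRUE`
#' (default) consecutive rounds are joined by drift continuity: the
#' extrapolated end of round `r - 1` becomes the start value of round `r`,
#' which is appropriate when the stage drifts continuously through buffer
#' exchanges. With `chain_rounds = FALSE` every round is re-anchored to
#' zero at its first frame and inter-round offsets are left to
#' [align_rounds()].
#'
#' @param table A `localization_table` (drift-uncorrected).
#' @param n_segments Temporal blocks per round (>= 2).
#' @param bin_size Rendering bin (nm).
#' @param blur_sigma Rendering blur (nm).
#' @param min_locs_per_segment Minimum localizations per block.
#' @param chain_rounds Join rounds by drift continuity (see Details).
#' @return A `drift_trajectory` covering all frames of all rounds present.
#' @export
estimate_drift_rcc <- function(table, n_segments = 10L, bin_size = 5,
                               blur_sigma = 10, min_locs_per_segment = 50L,
                               chain_rounds = TRUE) {
  stopifnot(inherits(table, "localization_table"), n_segments >= 2)
  F <- attr(table, "frames_per_round")
  if (is.na(F)) stop("table lacks frames_per_round attribute")
  rounds <- sort(unique(table$round))
  n_total <- (max(rounds) + 1L) * F
  dx <- numeric(n_total); dy <- numeric(n_total)
  extent <- c(min(table$x) - 3 * blur_sigma, max(table$x) + 3 * blur_sigma,
              min(table$y) - 3 * blur_sigma, max(table$y) + 3 * blur_sigma)
  for (r in rounds) {
    d <- table[table$round == r, , drop = FALSE]
    fr <- d$frame - r * F                      # within-round frame
    seg_len <- F / n_segments
    seg <- pmin(floor(fr / seg_len), n_segments - 1L)
    counts <- tabulate(seg + 1L, nbins = n_segments)
    low <- which(counts < min_locs_per_segment)
    if (length(low))
      stop("segment ", low[1] - 1L, " of round ", r, " has only ",
           counts[low[1]], " localizations (need ",
           min_locs_per_segment, ")")
    imgs <- lapply(seq_len(n_segments) - 1L, function(s)
      render_histogram(d[seg == s, , drop = FALSE], bin_size, blur_sigma,
                       extent)$pixels)
    pairs_i <- integer(0); pairs_j <- integer(0)
    sx <- numeric(0); sy <- numeric(0)
    for (i in seq_len(n_segments - 1L)) for (j in (i + 1L):n_segments) {
      sh <- xcorr_shift(imgs[[j]], imgs[[i]])
      if (is.null(sh)) {
        warning("flat correlation surface for blocks ", i - 1L, ",", j - 1L,
                " of round ", r, "; pair dropped")
        next
      }
      pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
      sx <- c(sx, sh[1] * bin_size); sy <- c(sy, sh[2] * bin_size)
    }
    # least squares for block displacements, block 1 anchored at 0:
    # shift(j over i) = d_j - d_i
    A <- matrix(0, length(pairs_i), n_segments - 1L)
    for (k in seq_along(pairs_i)) {
      if (pairs_j[k] > 1L) A[k, pairs_j[k] - 1L] <- 1
      if (pairs_i[k] > 1L) A[k, pairs_i[k] - 1L] <- -1
    }
    bx <- c(0, stats::lsfit(A, sx, intercept = FALSE)$coefficients)
    by <- c(0, stats::lsfit(A, sy, intercept = FALSE)$coefficients)
    centers <- (seq_len(n_segments) - 0.5) * seg_len   # block centre frames
    frames <- seq_len(F) - 1L
    ex <- interp_extrap(centers, bx, frames)
    ey <- interp_extrap(centers, by, frames)
    ex <- ex - ex[1]; ey <- ey - ey[1]       # anchor round start at zero
    if (chain_rounds && r > rounds[1]) {
      # continuity across the boundary: previous round's extrapolated end
      prev_end_x <- dx[r * F]; prev_end_y <- dy[r * F]
      prev_slope_x <- dx[r * F] - dx[r * F - 1L]
      prev_slope_y <- dy[r * F] - dy[r * F - 1L]
      ex <- ex + prev_end_x + prev_slope_x
      ey <- ey + prev_end_y + prev_slope_y
    }
    idx <- r * F + seq_len(F)
    dx[idx] <- ex; dy[idx] <- ey
  }
  structure(data.frame(dx = dx, dy = dy),
            class = c("drift_trajectory", "data.frame"))
}

# linear interpolation with linear extrapolation at both ends
interp_extrap <- function(xk, yk, x) {
  y <- stats::approx(xk, yk, xout = x, rule = 2)$y
  n <- length(xk)
  if (n >= 2) {
    s1 <- (yk[2] - yk[1]) / (xk[2] - xk[1])
    s2 <- (yk[n] - yk[n - 1]) / (xk[n] - xk[n - 1])
    lo <- x < xk[1]; hi <- x > xk[n]
    y[lo] <- yk[1] + s1 * (x[lo] - xk[1])
    y[hi] <- yk[n] + s2 * (x[hi] - xk[n])
  }
  y
}

#' Apply (subtract) a drift trajectory
#'
#' `x' = x - dx(frame)`, `y' = y - dy(frame)`. Applying twice is refused via
#' the `drift_corrected` flag.
#'
#' @param table A `localization_table`.
#' @param drift A `drift_trajectory` covering all frames in `table`.
#' @return The corrected table with `drift_corrected = TRUE`.
#' @export
apply_drift <- function(table, drift) {
  stopifnot(inherits(table, "localization_table"))
  if (isTRUE(attr(table, "drift_corrected")))
    stop("table is already drift-corrected")
  if (nrow(table) && max(table$frame) + 1L > nrow(drift))
    stop("drift trajectory does not cover all frames")
  at <- loc_attrs(table)
  df <- as.data.frame(table)
  df$x <- df$x - drift$dx[df$frame + 1L]
  df$y <- df$y - drift$dy[df$frame + 1L]
  at$drift_corrected <- TRUE
  restore_loc_attrs(df, at)
}

#' Align imaging rounds by rigid translation
#'
#' Renders each round as a blurred histogram and cross-correlates it against
#' the reference round; the negated, sub-bin interpolated peak shift is
#' applied as a rigid corrective translation (`x' = x + tx`). Rotation and scale are assumed stable across
#' rounds (same instrument and field), as is standard for exchange-style
#' multiplexing.
#'
#' @param table A drift-corrected `localization_table` with every round
#'   non-empty.
#' @param reference_round Round index all others are mapped onto.
#' @param bin_size Rendering bin (nm).
#' @param blur_sigma Rendering blur (nm).
#' @param min_correlation Floor on the normalised correlation peak below
#'   which a round is declared non-overlapping (error).
#' @param max_shift_nm Largest plausible rigid inter-round shift; a larger
#'   measured shift means the round shares no genuine overlap with the
#'   reference (mechanical shifts between rounds are tens of nm) and is an
#'   error.
#' @return List with `transforms` (data.frame: round, tx, ty in nm; the
#'   reference row is (0, 0)) and `table` (aligned, `rounds_aligned = TRUE`).
#' @export
align_rounds <- function(table, reference_round = 0L, bin_size = 5,
                         blur_sigma = 10, min_correlation = 0.05,
                         max_shift_nm = 500) {
  stopifnot(inherits(table, "localization_table"))
  rounds <- sort(unique(table$round))
  if (!reference_round %in% rounds)
    stop("reference round ", reference_round, " not present")
  extent <- c(min(table$x) - 3 * blur_sigma, max(table$x) + 3 * blur_sigma,
              min(table$y) - 3 * blur_sigma, max(table$y) + 3 * blur_sigma)
  imgs <- lapply(rounds, function(r)
    render_histogram(table[table$round == r, , drop = FALSE],
                     bin_size, blur_sigma, extent)$pixels)
  names(imgs) <- as.character(rounds)
  ref <- imgs[[as.character(reference_round)]]
  tx <- ty <- numeric(length(rounds))
  for (k in seq_along(rounds)) {
    r <- rounds[k]
    if (r == reference_round) next
    A <- imgs[[k]]
    peak_norm <- max(Re(stats::fft(stats::fft(A) * Conj(stats::fft(ref)),
                                   inverse = TRUE))) /
      (sqrt(sum(A^2) * sum(ref^2)) * length(A))
    if (!is.finite(peak_norm) || peak_norm < min_correlation)
      stop("round ", r, " shares no spatial overlap with reference round ",
           reference_round)
    sh <- xcorr_shift(A, ref)
    if (is.null(sh))
      stop("degenerate correlation between round ", r, " and reference")
    if (max(abs(sh)) * bin_size > max_shift_nm)
      stop("round ", r, " shares no spatial overlap with reference round ",
           reference_round, " (apparent shift ",
           round(max(abs(sh)) * bin_size), " nm exceeds ", max_shift_nm,
           " nm)")
    # corrective translation: x' = x + tx maps the round onto the reference
    tx[k] <- -sh[1] * bin_size
    ty[k] <- -sh[2] * bin_size
  }
  at <- loc_attrs(table)
  df <- as.data.frame(table)
  for (k in seq_along(rounds)) {
    sel <- df$round == rounds[k]
    df$x[sel] <- df$x[sel] + tx[k]
    df$y[sel] <- df$y[sel] + ty[k]
  }
  at$rounds_aligned <- TRUE
  list(transforms = data.frame(round = rounds, tx = tx, ty = ty),
       table = restore_loc_attrs(df, at))
}
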