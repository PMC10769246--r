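#' Place DNA docking sites along each species' layer
#'
#' Candidate sites are laid along each species' offset polyline as a
#' one-dimensional Poisson process with the species' linear density, thinned
#' independently by the labeling efficiency, then displaced per coordinate by
#' Gaussian noise of sd `sqrt(membrane_jitter_sigma^2 + linkage_sigma^2)`.
#' The jitter term models epitope spread around the ideal layer; the linkage
#' term models the antibody/nanobody arm between epitope and docking strand.
#'
#' @param geom A `golgi_geometry`.
#' @param labeling_efficiency Fraction of candidate sites that carry a
#'   docking strand, in (0, 1].
#' @param linkage_sigma Per-coordinate linkage-error sd (nm, >= 0).
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A `binding_site_set`: data.frame with `species_id` (0-based index
#'   into the panel; round `r` images species `r`), `x`, `y` (nm). Attribute
#'   `geometry` keeps the generating geometry.
#' @export
place_binding_sites <- function(geom, labeling_efficiency = 1,
                                linkage_sigma = 0, seed = 1L) {
  stopifnot(inherits(geom, "golgi_geometry"))
  if (!(labeling_efficiency > 0 && labeling_efficiency <= 1))
    stop("labeling_efficiency must be in (0, 1]")
  if (linkage_sigma < 0) stop("linkage_sigma must be >= 0")
  set.seed(as.integer(seed))
  pn <- geom$panel
  parts <- vector("list", nrow(pn))
  for (i in seq_len(nrow(pn))) {
    layer <- layer_polyline(geom, i)
    len <- polyline_length(layer)
    n_cand <- stats::rpois(1, pn$site_linear_density[i] * len / 1000)
    keep <- if (n_cand > 0)
      stats::runif(n_cand) < labeling_efficiency else logical(0)
    n <- sum(keep)
    if (n == 0) {
      parts[[i]] <- data.frame(species_id = integer(0),
                               x = numeric(0), y = numeric(0))
      next
    }
    s <- sort(stats::runif(n_cand, 0, len))[keep]
    p <- polyline_point(layer, s)
    sd_tot <- sqrt(pn$membrane_jitter_sigma[i]^2 + linkage_sigma^2)
    parts[[i]] <- data.frame(
      species_id = rep.int(i - 1L, n),
      x = p[, 1] + stats::rnorm(n, 0, sd_tot),
      y = p[, 2] + stats::rnorm(n, 0, sd_tot))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no binding sites generated for any species")
  structure(out, geometry = geom, class = c("binding_site_set", "data.frame"))
}
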