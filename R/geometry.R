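#' Species specification for a layered Golgi panel
#'
#' One row per target species: its name, where its layer sits relative to the
#' ribbon backbone, and how densely and how precisely it is decorated with
#' DNA docking sites.
#'
#' @param name Species label (e.g. `"GM130"`). Must be unique within a panel.
#' @param axial_offset Offset (nm) along the local stack normal, positive
#'   toward the trans face.
#' @param lateral_offset Offset (nm) along the ribbon tangent.
#' @param site_linear_density Docking sites per micrometre of ribbon (> 0).
#' @param membrane_jitter_sigma Per-coordinate Gaussian spread (nm) of
#'   epitopes around the ideal layer line (>= 0).
#'
#' @return A one-row `data.frame` with the five fields above.
#' @export
species_spec <- function(name, axial_offset, lateral_offset = 0,
                         site_linear_density = 150,
                         membrane_jitter_sigma = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(site_linear_density) || site_linear_density <= 0)
    stop("site_linear_density must be > 0 for species '", name, "'")
  if (!is.finite(membrane_jitter_sigma) || membrane_jitter_sigma < 0)
    stop("membrane_jitter_sigma must be >= 0 for species '", name, "'")
  data.frame(name = name,
             axial_offset = as.numeric(axial_offset),
             lateral_offset = as.numeric(lateral_offset),
             site_linear_density = as.numeric(site_linear_density),
             membrane_jitter_sigma = as.numeric(membrane_jitter_sigma),
             stringsAsFactors = FALSE)
}

#' Build a layered Golgi ribbon geometry
#'
#' Constructs the ground-truth geometry the simulator decorates with docking
#' sites: a 2-D ribbon backbone polyline plus a panel of species, each offset
#' from the backbone along the stack normal (cis -> trans) and/or the ribbon
#' tangent. Two presets are provided:
#'
#' * `"two_layer"`: two straight parallel ribbons separated by `delta` nm —
#'   the minimal layer-separation phantom.
#' * `"golgi7"`: a seven-species panel whose default axial offsets reproduce
#'   the qualitative cis -> trans ordering of common Golgi markers
#'   (GM130 0, GRASP65 10, VPS13B 30, Giantin 80, Golgin97 190, TGN46 210 nm;
#'   beta-COP off-stack on the cis side and laterally displaced). These
#'   defaults are a configurable phantom, not measured ultrastructure.
#'
#' The species panel order defines the imaging-round order: round `r`
#' (0-based) images species `r`.
#'
#' @param config A list. Either `list(preset = "two_layer", ...)`,
#'   `list(preset = "golgi7", ...)`, or an explicit
#'   `list(backbone = <n x 2 matrix, nm>, panel = <data.frame of species_spec
#'   rows>, field_size = c(w, h))`.
#'   Preset options: `delta` (two_layer layer separation, nm, default 60),
#'   `length` (ribbon length, nm, default 4000), `site_linear_density`,
#'   `membrane_jitter_sigma`, `field_size`, and for `golgi7` a named numeric
#'   `axial_offsets` override plus a `species` character subset (kept in
#'   panel order).
#'
#' @return An object of class `golgi_geometry`: list with `backbone`
#'   (n x 2 matrix, nm), `panel` (data.frame), `field_size` (w, h in nm).
#' @export
build_geometry <- function(config = list(preset = "two_layer")) {
  stopifnot(is.list(config))
  if (!is.null(config$preset)) {
    geom <- switch(config$preset,
      two_layer = preset_two_layer(config),
      golgi7 = preset_golgi7(config),
      stop("unknown geometry preset: ", config$preset)
    )
  } else {
    if (is.null(config$backbone) || is.null(config$panel))
      stop("geometry config needs a preset or explicit backbone + panel")
    geom <- new_geometry(as.matrix(config$backbone), config$panel,
                         config$field_size)
  }
  validate_geometry(geom)
}

preset_two_layer <- function(config) {
  delta <- config$delta %||% 60
  len <- config$length %||% 4000
  dens <- config$site_linear_density %||% 200
  jitter <- config$membrane_jitter_sigma %||% 0
  field <- config$field_size %||% c(len + 2000, 2000)
  y0 <- field[2] / 2
  backbone <- cbind(x = c(1000, 1000 + len), y = c(y0, y0))
  panel <- rbind(
    species_spec("layerA", 0, 0, dens, jitter),
    species_spec("layerB", delta, 0, dens, jitter)
  )
  new_geometry(backbone, panel, field)
}

#' @rdname build_geometry
#' @format NULL
golgi7_default_offsets <- c(GM130 = 0, GRASP65 = 10, VPS13B = 30,
                            Giantin = 80, Golgin97 = 190, TGN46 = 210,
                            bCOP = -80)

preset_golgi7 <- function(config) {
  off <- golgi7_default_offsets
  if (!is.null(config$species)) {
    bad <- setdiff(config$species, names(off))
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    off <- off[names(off) %in% config$species]
  }
  if (!is.null(config$axial_offsets)) {
    ov <- config$axial_offsets
    bad <- setdiff(names(ov), names(off))
    if (length(bad)) stop("unknown species in axial_offsets: ",
                          paste(bad, collapse = ", "))
    off[names(ov)] <- unlist(ov)
  }
  len <- config$length %||% 4000
  dens <- config$site_linear_density %||% 150
  jitter <- config$membrane_jitter_sigma %||% 5
  field <- config$field_size %||% c(len + 2000, 2000)
  y0 <- field[2] / 2
  backbone <- cbind(x = c(1000, 1000 + len), y = c(y0, y0))
  panel <- do.call(rbind, lapply(names(off), function(nm) {
    species_spec(nm, off[[nm]],
                 lateral_offset = if (nm == "bCOP") 300 else 0,
                 site_linear_density = dens,
                 membrane_jitter_sigma = jitter)
  }))
  new_geometry(backbone, panel, field)
}

new_geometry <- function(backbone, panel, field_size) {
  backbone <- as.matrix(backbone)
  storage.mode(backbone) <- "double"
  colnames(backbone) <- c("x", "y")
  structure(list(backbone = backbone,
                 panel = as.data.frame(panel),
                 field_size = as.numeric(field_size)),
            class = "golgi_geometry")
}

#' Validate a Golgi geometry
#'
#' Checks backbone shape, species-name uniqueness, per-species invariants,
#' and that every species' offset layer polyline lies inside the field.
#'
#' @param geom A `golgi_geometry`.
#' @return `geom`, invisibly unchanged, or an error naming the offender.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "golgi_geometry"))
  bb <- geom$backbone
  if (nrow(bb) < 2) stop("backbone must have >= 2 points")
  if (!all(is.finite(bb))) stop("backbone coordinates must be finite")
  fs <- geom$field_size
  if (length(fs) != 2 || any(!is.finite(fs)) || any(fs <= 0))
    stop("field_size must be two positive lengths (nm)")
  inside <- function(p) all(p[, 1] >= 0 & p[, 1] <= fs[1] &
                            p[, 2] >= 0 & p[, 2] <= fs[2])
  if (!inside(bb)) stop("backbone lies outside field_size")
  pn <- geom$panel
  if (anyDuplicated(pn$name)) stop("species names must be unique")
  if (any(pn$site_linear_density <= 0)) stop("site_linear_density must be > 0")
  if (any(pn$membrane_jitter_sigma < 0)) stop("membrane_jitter_sigma must be >= 0")
  for (i in seq_len(nrow(pn))) {
    if (!inside(layer_polyline(geom, i)))
      stop("layer for species '", pn$name[i], "' lies outside field_size")
  }
  geom
}

#' Offset layer polyline for one species
#'
#' Displaces each backbone vertex along the local (vertex-averaged) tangent by
#' the species' lateral offset and along the local normal by its axial offset.
#' The normal is the tangent rotated +90 degrees in the image frame (x right,
#' y down), so positive axial offsets move toward larger y on a left-to-right
#' backbone.
#'
#' @param geom A `golgi_geometry`.
#' @param species_index 1-based row index into `geom$panel`.
#' @return An n x 2 matrix of layer vertices (nm).
#' @export
layer_polyline <- function(geom, species_index) {
  bb <- geom$backbone
  sp <- geom$panel[species_index, ]
  n <- nrow(bb)
  seg <- diff(bb)
  seg <- seg / sqrt(rowSums(seg^2))
  # per-vertex tangent: average of adjacent segment directions
  tang <- rbind(seg[1, , drop = FALSE],
                if (n > 2) (seg[-nrow(seg), , drop = FALSE] +
                            seg[-1, , drop = FALSE]) / 2,
                seg[nrow(seg), , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  norm <- cbind(-tang[, 2], tang[, 1])
  out <- bb + sp$lateral_offset * tang + sp$axial_offset * norm
  colnames(out) <- c("x", "y")
  out
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# point at arclength s along polyline p (vectorised over s)
polyline_point <- function(p, s) {
  seglen <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seglen))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  k <- pmin(k, length(seglen))
  f <- (s - cum[k]) / seglen[k]
  cbind(x = p[k, 1] + f * (p[k + 1, 1] - p[k, 1]),
        y = p[k, 2] + f * (p[k + 1, 2] - p[k, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.golgi_geometry <- function(x, ...) {
  cat("golgi_geometry:", nrow(x$panel), "species, backbone of",
      nrow(x$backbone), "points, field",
      paste(x$field_size, collapse = " x "), "nm\n")
  print(x$panel, row.names = FALSE)
  invisible(x)
}
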