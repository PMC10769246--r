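#' Read a localization table from CSV
#'
#' The native table format is CSV with a `# key: value` header block
#' (written by [write_localizations()]) carrying `units`, `pixel_size` and
#' `frames_per_round`. Columns in pixel units (`units: px`) are converted to
#' nm with the recorded pixel size. Mandatory columns: `frame`, `round`,
#' `x`, `y`, `photons`, `loc_precision`.
#'
#' @param path CSV path.
#' @return A `localization_table` in nm.
#' @export
read_localizations <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("frame", "round", "x", "y", "photons", "loc_precision")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  units <- meta$units %||% "nm"
  px <- as.numeric(meta$pixel_size %||% NA)
  if (units == "px") {
    if (!is.finite(px)) stop("pixel-unit table without pixel_size header")
    df$x <- df$x * px
    df$y <- df$y * px
    df$loc_precision <- df$loc_precision * px
  } else if (units != "nm") stop("unknown units: ", units)
  as_localization_table(
    df, pixel_size = px,
    frames_per_round = as.integer(meta$frames_per_round %||% NA),
    drift_corrected = identical(meta$drift_corrected, "TRUE"),
    rounds_aligned = identical(meta$rounds_aligned, "TRUE"))
}

#' Write a localization table to CSV
#'
#' @param table A `localization_table`.
#' @param path Output path.
#' @param units `"nm"` (native) or `"px"` (Picasso-style interoperability
#'   export; requires a known pixel size).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, units = c("nm", "px")) {
  stopifnot(inherits(table, "localization_table"))
  units <- match.arg(units)
  df <- as.data.frame(table)
  px <- attr(table, "pixel_size")
  if (units == "px") {
    if (!is.finite(px)) stop("pixel export requires a known pixel_size")
    df$x <- df$x / px
    df$y <- df$y / px
    df$loc_precision <- df$loc_precision / px
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# units: ", units),
    paste0("# pixel_size: ", px),
    paste0("# frames_per_round: ", attr(table, "frames_per_round")),
    paste0("# drift_corrected: ", isTRUE(attr(table, "drift_corrected"))),
    paste0("# rounds_aligned: ", isTRUE(attr(table, "rounds_aligned")))),
    con)
  # full 17-significant-digit formatting so coordinates round-trip
  # bit-exactly through the text format
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The fully-defaulted configuration is itself valid: a two-layer list-mode
#' simulation followed by drift correction, round alignment and the
#' proximity matrix. Sections: `mode` (`"list"` or `"frame"`), `seed`,
#' `geometry`, `labeling`, `imaging`, `drift`, `localization`,
#' `registration`, `proximity`.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "list",
    seed = 1L,
    geometry = list(preset = "two_layer", delta = 60, length = 4000,
                    site_linear_density = 200, membrane_jitter_sigma = 0),
    labeling = list(labeling_efficiency = 1, linkage_sigma = 0),
    imaging = list(n_rounds = 2L, frames_per_round = 3000L,
                   exposure_ms = 25, mean_bright_frames = 3,
                   mean_dark_frames = 500, photons_per_frame = 300,
                   background_photons = 5, psf_sigma = 130,
                   pixel_size = 108, eraser_residual = 0),
    drift = list(step_sigma = 0.05, linear_velocity = c(0.01, 0)),
    localization = list(threshold_k = 5, max_gap = 1, link_max_dist = 100),
    registration = list(n_segments = 10L, bin_size = 5, blur_sigma = 10,
                        chain_rounds = TRUE, align = FALSE,
                        reference_round = 0L),
    proximity = list(r_max = 500, mode = "nn", min_pairs = 10L,
                     n_boot = 200L)
  )
}

#' Load and validate a run configuration
#'
#' Reads YAML (or takes a list), merges it over [default_config()], and
#' rejects unknown keys at any level.
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return Completed configuration list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  merge_config(default_config(), config, path = "")
}

# keys legal in the geometry section beyond the two_layer defaults
# (preset-dependent: golgi7 overrides and explicit backbone + panel)
geometry_extra_keys <- c("axial_offsets", "species", "backbone", "panel",
                         "field_size")

merge_config <- function(base, user, path) {
  allowed <- names(base)
  if (path == ".geometry") allowed <- c(allowed, geometry_extra_keys)
  extra <- setdiff(names(user), allowed)
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, ".", nm))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Dump a configuration as YAML text
#'
#' @param config A config list (defaults used when omitted).
#' @return YAML character scalar, invisibly; also printed.
#' @export
dump_config <- function(config = default_config()) {
  txt <- yaml::as.yaml(config)
  cat(txt)
  invisible(txt)
}
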