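#' Run the full simulation + analysis pipeline
#'
#' Executes simulate -> (localize, frame mode only) -> blink linking ->
#' drift correction -> round alignment -> distance matrix -> report, writing
#' all outputs and a run manifest under `out_dir`. Every stage draws its
#' randomness from a stage-specific seed fanned out deterministically from
#' the master seed (`set.seed(master)` then one `sample.int` draw per
#' stage, in fixed stage order), so stages can be reproduced in isolation;
#' the fan-out is recorded in the manifest.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("flashrun")) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))
  stage_names <- c("sites", "blinking", "drift", "render", "localize",
                   "proximity")
  seeds <- stats::setNames(sample.int(.Machine$integer.max, length(stage_names)),
                           stage_names)
  counters <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  geom <- stage("geometry", build_geometry(cfg$geometry))
  imaging <- do.call(imaging_params, cfg$imaging)
  sites <- stage("sites", place_binding_sites(
    geom, cfg$labeling$labeling_efficiency, cfg$labeling$linkage_sigma,
    seed = seeds["sites"]))
  counters$n_sites <- nrow(sites)
  events <- stage("blinking", simulate_rounds(sites, imaging,
                                              seed = seeds["blinking"]))
  counters$n_events <- nrow(events)
  n_total <- imaging$n_rounds * imaging$frames_per_round
  drift <- stage("drift", simulate_drift(
    n_total, cfg$drift$step_sigma, unlist(cfg$drift$linear_velocity),
    seed = seeds["drift"]))

  if (cfg$mode == "frame") {
    field_px <- ceiling(geom$field_size / imaging$pixel_size)
    stack <- stage("render", render_movie(events, sites, drift, imaging,
                                          field_px, seed = seeds["render"]))
    tab <- stage("localize", localize_movie(stack, cfg$localization$threshold_k))
    counters$n_dropped_fits <- attr(tab, "n_dropped_fits")
  } else if (cfg$mode == "list") {
    tab <- stage("localize", events_to_localizations(
      events, sites, drift, imaging, seed = seeds["localize"]))
    counters$n_dropped_zero_photon <- attr(tab, "n_dropped_zero_photon")
  } else stop("mode must be 'list' or 'frame'")
  counters$n_localizations <- nrow(tab)

  tab <- stage("link", link_blinks(tab, cfg$localization$max_gap,
                                   cfg$localization$link_max_dist))
  counters$n_linked <- nrow(tab)

  est_drift <- stage("rcc", estimate_drift_rcc(
    tab, cfg$registration$n_segments, cfg$registration$bin_size,
    cfg$registration$blur_sigma,
    chain_rounds = isTRUE(cfg$registration$chain_rounds)))
  tab <- stage("apply_drift", apply_drift(tab, est_drift))
  if (isTRUE(cfg$registration$align)) {
    ali <- stage("align", align_rounds(tab, cfg$registration$reference_round,
                                       cfg$registration$bin_size,
                                       cfg$registration$blur_sigma))
    tab <- ali$table
  } else {
    # structural alignment between rounds imaging different layers is
    # degenerate (it removes the true inter-layer offset); rounds are
    # joined by drift-continuity chaining in the RCC stage instead
    at <- loc_attrs(tab); at$rounds_aligned <- TRUE
    tab <- restore_loc_attrs(as.data.frame(tab), at)
    ali <- list(transforms = data.frame(round = sort(unique(tab$round)),
                                        tx = 0, ty = 0))
  }

  if (cfg$mode == "frame") {
    # frame-mode tables carry no ground-truth species; assign by round
    tab$species <- tab$round
  }
  prox <- proximity_params(cfg$proximity$r_max, cfg$proximity$mode,
                           cfg$proximity$min_pairs, cfg$proximity$n_boot)
  dm <- stage("proximity", distance_matrix(
    tab, prox, species_labels = geom$panel$name, seed = seeds["proximity"]))
  counters$n_distance_pairs <- sum(dm$n_pairs)

  write_localizations(tab, file.path(out_dir, "localizations.csv"))
  utils::write.csv(data.frame(frame = seq_len(nrow(est_drift)) - 1L,
                              est_drift),
                   file.path(out_dir, "drift.csv"), row.names = FALSE)
  utils::write.csv(ali$transforms, file.path(out_dir, "round_transforms.csv"),
                   row.names = FALSE)
  write_distance_matrix(dm, file.path(out_dir, "distance_matrix.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("flashpaint")),
    config = cfg,
    config_hash = config_hash(cfg),
    stage_seeds = as.list(seeds),
    counters = counters,
    timings_s = timings,
    outputs = list(localizations = "localizations.csv",
                   drift = "drift.csv",
                   transforms = "round_transforms.csv",
                   matrix = "distance_matrix.csv",
                   summary = "summary.json",
                   figure = "distance_matrix.png"))
  report(dm, manifest, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a distance matrix as a tidy CSV of ordered pairs
#'
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  k <- length(dm$labels)
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  df <- data.frame(
    from = dm$labels[idx$i], to = dm$labels[idx$j],
    median_nm = dm$median[cbind(idx$i, idx$j)],
    n_pairs = dm$n_pairs[cbind(idx$i, idx$j)],
    ci_low_nm = dm$ci_low[cbind(idx$i, idx$j)],
    ci_high_nm = dm$ci_high[cbind(idx$i, idx$j)],
    valid = dm$valid[cbind(idx$i, idx$j)])
  df <- df[order(df$from, df$to), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Report a distance matrix: heat map, ranking and JSON summary
#'
#' Writes `distance_matrix.png` (median heat map, invalid cells crossed
#' out), `ranking.csv` (targets ranked from the first panel species), and
#' `summary.json` mirroring every number in the figure.
#'
#' @param dm A `distance_matrix`.
#' @param manifest The run manifest list (echoed into the summary), or
#'   `NULL`.
#' @param out_dir Output directory.
#' @param reference_species Species whose ranking is tabulated; defaults to
#'   the first label.
#' @return Path of the JSON summary, invisibly.
#' @export
report <- function(dm, manifest = NULL, out_dir = ".",
                   reference_species = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- length(dm$labels)
  ref <- reference_species %||% dm$labels[1]
  ranking <- tryCatch(rank_targets(dm, ref), error = function(e) NULL)

  png_path <- file.path(out_dir, "distance_matrix.png")
  grDevices::png(png_path, width = 720, height = 640)
  op <- graphics::par(mar = c(6, 6, 3, 5))
  z <- dm$median
  zplot <- t(z)[, k:1, drop = FALSE]
  graphics::image(seq_len(k), seq_len(k), zplot,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("Median cross-target distance (nm), %s mode, r <= %g nm",
                                 dm$params$mode, dm$params$r_max))
  graphics::axis(1, seq_len(k), dm$labels, las = 2)
  graphics::axis(2, seq_len(k), rev(dm$labels), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    yy <- k - i + 1
    if (dm$valid[i, j])
      graphics::text(j, yy, sprintf("%.0f", dm$median[i, j]), cex = 0.9)
    else {
      graphics::text(j, yy, "x", cex = 1.2)
      graphics::segments(j - 0.4, yy - 0.4, j + 0.4, yy + 0.4)
    }
  }
  graphics::par(op)
  grDevices::dev.off()

  mat_list <- function(m) {
    out <- as.list(as.data.frame(m))
    stats::setNames(out, dm$labels)
  }
  summary <- list(
    labels = dm$labels,
    params = unclass(dm$params),
    median_nm = apply(dm$median, 1, as.list),
    n_pairs = apply(dm$n_pairs, 1, as.list),
    ci_low_nm = apply(dm$ci_low, 1, as.list),
    ci_high_nm = apply(dm$ci_high, 1, as.list),
    valid = apply(dm$valid, 1, as.list),
    ranking = if (!is.null(ranking)) ranking else NULL,
    reference_species = ref,
    config_hash = manifest$config_hash)
  if (!is.null(ranking))
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(json_path)
}
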