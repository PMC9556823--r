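pipeline_defaults <- function() {
  list(
    decay_tiff = NULL, decay_meta = NULL,      # input cube (+ sidecar)
    aux_tiff = list(),                         # named list of aux TIFF paths
    calibration_csv = NULL,                    # (pH, G) table; NULL = reference line
    harmonic = 1, bin_factor = 1, min_photons = 15,
    percentile_low = 25, percentile_high = 99.8,
    prob_threshold = 0.5, overlap_threshold = 0,
    max_area_um2 = 2, erode_iterations = 0, mode_bin = 0.1,
    out_dir = ".", seed = 1L, log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()] from a named list
#' or a JSON file. Unknown keys are rejected; all printed analysis defaults
#' (spatial bin, 15 photon/pixel threshold, 2 um^2 area cutoff, percentiles
#' 25/99.8, probability threshold 0.5, overlap 0) are pre-filled.
#'
#' @param config Named list of settings, or a path to a JSON file of them.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown pipeline config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$decay_tiff)) abort("pipeline config needs `decay_tiff`.")
  for (k in c("harmonic", "bin_factor", "min_photons", "erode_iterations"))
    if (cfg[[k]] < 0) abort(sprintf("config `%s` must be non-negative.", k))
  if (!cfg$log_level %in% c("debug", "info", "warn"))
    abort("`log_level` must be one of debug/info/warn.")
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(lines, level, msg, ...) {
  entry <- sprintf("[%s] %s", level, sprintf(msg, ...))
  c(lines, entry)
}

#' Run the end-to-end vesicle pH pipeline
#'
#' Reads a decay cube, computes per-pixel phasors, applies the photon
#' threshold, detects vesicles in the photon-count image, applies the area
#' and erosion post-filters, quantifies per-vesicle pH through the
#' calibration, and writes the output bundle: vesicle CSV, image-summary
#' CSV, a pH-coloured mask image (PNG via ggplot2), a photon-weighted G
#' histogram CSV, the resolved configuration and a stage log. Deterministic
#' given inputs and config.
#'
#' @param config A [pipeline_config()] (or list/JSON path coercible to one).
#' @return Invisibly, a list with the `vesicles` and `summary` tibbles and
#'   the output file paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lg <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  decay <- stage("read", read_decay_tiff(config$decay_tiff, config$decay_meta))
  lg <- pipe_log(lg, "info", "read decay cube %s (%d x %d x %d)",
                 config$decay_tiff, dim(decay)[1], dim(decay)[2], dim(decay)[3])

  if (config$bin_factor > 1) {
    decay <- stage("bin", spatial_bin(decay, config$bin_factor))
    lg <- pipe_log(lg, "info", "spatial bin factor %d", config$bin_factor)
  }
  phasor <- stage("phasor", compute_phasor(decay, harmonic = config$harmonic))
  phasor <- threshold_photons(phasor, config$min_photons)
  lg <- pipe_log(lg, "info", "phasor: harmonic %d, threshold %d photons, %d valid px",
                 config$harmonic, config$min_photons, sum(phasor$valid))

  cal <- stage("calibration", {
    if (is.null(config$calibration_csv)) default_g_calibration()
    else {
      tab <- read_calibration_csv(config$calibration_csv)
      fit_g_calibration(tibble(g = tab$value, ph = tab$ph))
    }
  })
  lg <- pipe_log(lg, "info", "calibration: pH = %.4g %+.4g G", cal$intercept, cal$slope)

  params <- segmentation_params(config$percentile_low, config$percentile_high,
                                config$prob_threshold, config$overlap_threshold)
  mask <- stage("segment", detect_vesicles(phasor$photons, params,
                                           pixel_size = decay$pixel_size))
  mask <- stage("filter", filter_labels(mask, phasor$photons,
                                        config$max_area_um2, config$min_photons))
  if (config$erode_iterations > 0)
    mask <- stage("erode", erode_labels(mask, config$erode_iterations))
  lg <- pipe_log(lg, "info", "segmentation: %d vesicle(s) after post-filters", n_labels(mask))

  aux <- list()
  for (nm in names(config$aux_tiff))
    aux[[nm]] <- stage("aux", tiff::readTIFF(config$aux_tiff[[nm]], as.is = TRUE))

  vesicles <- stage("quantify", vesicle_table(phasor, mask, cal, aux = aux))
  summary <- stage("summarise", {
    if (nrow(vesicles) > 0) summarize_image(vesicles, mode_bin = config$mode_bin)
    else tibble(mean_ph = NA_real_, modal_ph = NA_real_, majority_low = NA_real_,
                majority_high = NA_real_, n_vesicles = 0L,
                timepoint = NA_real_, condition = NA_character_)
  })

  paths <- list(
    vesicles = file.path(config$out_dir, "vesicles.csv"),
    summary = file.path(config$out_dir, "summary.csv"),
    g_histogram = file.path(config$out_dir, "g_histogram.csv"),
    ph_mask_png = file.path(config$out_dir, "ph_mask.png"),
    config = file.path(config$out_dir, "resolved_config.json"),
    log = file.path(config$out_dir, "pipeline.log"))
  write_phlimr_csv(vesicles, paths$vesicles, "phlimr/vesicles/v1")
  write_phlimr_csv(summary, paths$summary, "phlimr/summary/v1")
  g_hist <- phasor_g_histogram(phasor)
  write_phlimr_csv(g_hist, paths$g_histogram, "phlimr/g-histogram/v1")
  stage("render", {
    p <- plot_ph_mask(phasor, mask, cal)
    ggplot2::ggsave(paths$ph_mask_png, p, width = 6, height = 5, dpi = 120)
  })
  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(lg, paths$log)
  invisible(list(vesicles = vesicles, summary = summary, paths = paths,
                 mask = mask, calibration = cal))
}

#' Photon-weighted G histogram of an image
#'
#' @param phasor A `phasor_image`.
#' @param bin_width Histogram bin width in G (default 0.01).
#' @return Tibble with `g_mid` bin centres and photon `mass`.
#' @export
phasor_g_histogram <- function(phasor, bin_width = 0.01) {
  stopifnot(inherits(phasor, "phasor_image"))
  if (!any(phasor$valid)) return(tibble(g_mid = double(), mass = double()))
  g <- phasor$G[phasor$valid]
  w <- as.numeric(phasor$photons[phasor$valid])
  idx <- floor(g / bin_width + 1e-9)
  mass <- tapply(w, idx, sum)
  tibble(g_mid = (as.numeric(names(mass)) + 0.5) * bin_width,
         mass = as.numeric(mass))
}
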