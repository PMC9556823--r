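# On-disk formats: multi-page TIFF for cubes/images with JSON sidecars for
# metadata; CSV for tables and calibrations; JSON for fitted calibrations.

sidecar_path <- function(path, meta_path = NULL) {
  if (!is.null(meta_path)) meta_path else paste0(path, ".json")
}

#' Read and write decay cubes as multi-page TIFF + JSON sidecar
#'
#' A [decay_image()] is stored as a uint16 multi-page TIFF (one page per
#' time bin, page order = increasing time) with a JSON sidecar holding
#' `bin_width_ns`, `rep_rate_mhz`, `pixel_size_um`, `channel_name` and
#' `n_bins`. The round trip is bit-exact for counts up to 65535.
#'
#' @param decay A [decay_image()].
#' @param path TIFF file path.
#' @param meta_path Sidecar JSON path (default `<path>.json`).
#' @return `write_decay_tiff()` the path, invisibly; `read_decay_tiff()` a
#'   [decay_image()].
#' @export
write_decay_tiff <- function(decay, path, meta_path = NULL) {
  stopifnot(inherits(decay, "decay_image"))
  mx <- max(decay$counts)
  if (mx > 65535) abort("counts exceed the uint16 range of the decay TIFF format.")
  d <- dim(decay$counts)
  pages <- lapply(seq_len(d[3]), function(b) decay$counts[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(bin_width_ns = decay$bin_width, rep_rate_mhz = decay$rep_rate,
               pixel_size_um = decay$pixel_size, channel_name = decay$channel,
               n_bins = d[3])
  jsonlite::write_json(meta, sidecar_path(path, meta_path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_decay_tiff
#' @export
read_decay_tiff <- function(path, meta_path = NULL) {
  mp <- sidecar_path(path, meta_path)
  if (!file.exists(mp))
    abort(sprintf("missing metadata sidecar '%s' for decay TIFF '%s'.", mp, path))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in c("bin_width_ns", "rep_rate_mhz", "pixel_size_um", "n_bins"))
    if (is.null(meta[[f]])) abort(sprintf("decay metadata is missing field `%s`.", f))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    abort(sprintf("decay TIFF page count mismatch: metadata `n_bins` expects %d, file has %d.",
                  meta$n_bins, length(pages)))
  cube <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  decay_image(cube, meta$bin_width_ns, meta$rep_rate_mhz, meta$pixel_size_um,
              meta$channel_name %||% "mApple")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit TIFF page storage for real-valued grids: values are affinely
# rescaled to [0, 1] and the (offset, scale) recorded in the sidecar, which
# round-trips to ~1e-9 relative precision.
encode_real_page <- function(x) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  list(page = (x - lo) / scale, offset = lo, scale = scale)
}

#' Read and write phasor images as 3-page TIFF + JSON sidecar
#'
#' Pages hold G, S and photon counts; each page is stored as 32-bit samples
#' with an affine rescaling recorded in the sidecar (round trip accurate to
#' ~1e-9). The sidecar also carries `omega_rad_per_ns`, the pixel size and
#' the valid-pixel mask (run-length encoded as indices of invalid pixels).
#'
#' @param phasor A `phasor_image`.
#' @param path TIFF file path.
#' @param meta_path Sidecar JSON path (default `<path>.json`).
#' @return `write_phasor_tiff()` the path, invisibly; `read_phasor_tiff()`
#'   a `phasor_image`.
#' @export
write_phasor_tiff <- function(phasor, path, meta_path = NULL) {
  stopifnot(inherits(phasor, "phasor_image"))
  pg <- lapply(list(phasor$G, phasor$S, phasor$photons), encode_real_page)
  tiff::writeTIFF(lapply(pg, `[[`, "page"), path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(omega_rad_per_ns = phasor$omega, pixel_size_um = phasor$pixel_size,
               pages = c("G", "S", "photons"),
               offset = vapply(pg, `[[`, 0, "offset"),
               scale = vapply(pg, `[[`, 0, "scale"),
               invalid_idx = which(!phasor$valid))
  jsonlite::write_json(meta, sidecar_path(path, meta_path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phasor_tiff
#' @export
read_phasor_tiff <- function(path, meta_path = NULL) {
  mp <- sidecar_path(path, meta_path)
  if (!file.exists(mp)) abort(sprintf("missing metadata sidecar '%s'.", mp))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L)
    abort(sprintf("phasor TIFF must have 3 pages (G, S, photons); found %d.", length(pages)))
  dec <- function(i) pages[[i]] * meta$scale[i] + meta$offset[i]
  G <- dec(1); S <- dec(2); photons <- round(dec(3))
  valid <- matrix(TRUE, nrow(G), ncol(G))
  if (length(meta$invalid_idx)) valid[meta$invalid_idx] <- FALSE
  phasor_image(G, S, photons, meta$omega_rad_per_ns, valid,
               meta$pixel_size_um %||% 0.133)
}

#' Read and write label masks as uint16 TIFF
#'
#' @param mask A [label_mask()].
#' @param path TIFF path; pixel size goes in a JSON sidecar.
#' @param meta_path Sidecar path (default `<path>.json`).
#' @return The path invisibly / a [label_mask()].
#' @export
write_label_tiff <- function(mask, path, meta_path = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) abort("more than 65535 labels: uint16 overflow.")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size),
                       sidecar_path(path, meta_path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path, meta_path = NULL) {
  mp <- sidecar_path(path, meta_path)
  px <- if (file.exists(mp))
    jsonlite::read_json(mp, simplifyVector = TRUE)$pixel_size_um else 0.133
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_mask(m, px %||% 0.133, compact = FALSE)
}

#' Read a calibration table from CSV
#'
#' Expects columns `pH` (or `ph`), `value` (the measured G or normalised
#' intensity) and optionally `replicate`.
#'
#' @param path CSV path.
#' @return Tibble with columns `ph`, `value`, `replicate`.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  nm <- tolower(names(df))
  names(df) <- nm
  if (!all(c("ph", "value") %in% nm))
    abort("calibration CSV needs columns `pH` and `value`.")
  if (!"replicate" %in% nm) df$replicate <- 1L
  as_tibble(df[c("ph", "value", "replicate")])
}

#' Serialise fitted calibrations to and from JSON
#'
#' All fields of the fitted object (including band state / parameter
#' covariance) are written so a calibration can be re-used across sessions
#' without refitting.
#'
#' @param cal A `g_calibration` or `intensity_calibration`.
#' @param path JSON path.
#' @return The path invisibly / the restored calibration object.
#' @export
write_calibration_json <- function(cal, path) {
  type <- class(cal)[1]
  if (!type %in% c("g_calibration", "intensity_calibration"))
    abort("not a calibration object.")
  payload <- unclass(cal)
  payload$data <- as.data.frame(payload$data)
  if (!is.null(payload$fit_cov)) {
    cov_df <- as.data.frame(payload$fit_cov)
    rownames(cov_df) <- NULL   # column order carries the parameter order
    payload$fit_cov <- cov_df
  }
  jsonlite::write_json(list(type = type, fields = payload), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- obj$fields
  f$data <- as_tibble(as.data.frame(f$data))
  if (!is.null(f$fit_cov)) {
    cov_df <- as.data.frame(f$fit_cov)
    cov_df[["_row"]] <- NULL
    f$fit_cov <- as.matrix(cov_df)
    rownames(f$fit_cov) <- colnames(f$fit_cov)
  }
  structure(f, class = obj$type)
}

#' Write a table as schema-stamped CSV
#'
#' Package CSV outputs open with a `#`-comment header naming the schema and
#' version, so downstream scripts can check what they are reading.
#' [read_phlimr_csv()] skips the header.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param schema Schema string (e.g. `"phlimr/vesicles/v1"`).
#' @return The path invisibly / a tibble.
#' @export
write_phlimr_csv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: %s", schema), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phlimr_csv
#' @export
read_phlimr_csv <- function(path) {
  as_tibble(read.csv(path, comment.char = "#"))
}
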