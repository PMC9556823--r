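#' Integer-labelled vesicle mask
#'
#' A `label_mask` wraps an integer matrix in which 0 is background and each
#' positive value k marks the pixels of vesicle k. Labels are kept compact
#' (1..K). The pixel size is carried so areas can be reported in um^2.
#'
#' @param labels Non-negative integer matrix.
#' @param pixel_size Pixel size in micrometres.
#' @param compact Recompact label values to 1..K (default TRUE).
#' @return A `label_mask`.
#' @export
label_mask <- function(labels, pixel_size = 0.133, compact = TRUE) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  labels[] <- as.integer(round(labels))
  if (anyNA(labels) || any(labels < 0L))
    abort("`labels` must be non-negative integers (0 = background).")
  if (compact) labels <- compact_labels(labels)
  structure(list(labels = labels, pixel_size = pixel_size), class = "label_mask")
}

compact_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  labels[labels > 0L] <- map[labels[labels > 0L]]
  labels
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d region(s), pixel %.3f um\n",
              nrow(x$labels), ncol(x$labels), n_labels(x), x$pixel_size))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' Number of labelled regions in a mask
#' @param mask A [label_mask()].
#' @return Integer count of distinct regions.
#' @export
n_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  length(unique(mask$labels[mask$labels > 0L]))
}

#' Region table of a label mask
#'
#' @param mask A [label_mask()].
#' @return Tibble with `label`, `area_px`, `area_um2`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates).
#' @export
label_table <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  keep <- lab > 0L
  if (!any(keep)) {
    return(tibble(label = integer(), area_px = integer(), area_um2 = double(),
                  centroid_row = double(), centroid_col = double()))
  }
  rows <- row(lab)[keep] - 1; cols <- col(lab)[keep] - 1
  lk <- lab[keep]
  tibble(label = sort(unique(lk))) |>
    dplyr::mutate(area_px = as.integer(tabulate(lk)[.data$label]),
                  area_um2 = .data$area_px * mask$pixel_size^2,
                  centroid_row = as.numeric(tapply(rows, lk, mean)),
                  centroid_col = as.numeric(tapply(cols, lk, mean)))
}

#' Percentile-normalise an intensity image
#'
#' Linear rescale mapping the `p_low` percentile of the image to 0 and the
#' `p_high` percentile to 1 (values clipped to `[0, 1]`) — the input
#' normalisation applied before vesicle detection.
#'
#' @param img Numeric matrix.
#' @param p_low,p_high Percentiles in `[0, 100]` with `p_low < p_high`
#'   (defaults 25 and 99.8).
#' @return Numeric matrix in `[0, 1]`.
#' @export
normalize_percentiles <- function(img, p_low = 25, p_high = 99.8) {
  if (!is.matrix(img)) abort("`img` must be a matrix.")
  if (!(p_low < p_high)) abort("`p_low` must be smaller than `p_high`.")
  q <- quantile(img, c(p_low, p_high) / 100, names = FALSE, na.rm = FALSE)
  if (q[2] <= q[1])
    abort("image is constant over the requested percentile range: cannot normalise.")
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Segmentation parameter set
#'
#' Parameters of [detect_vesicles()]. The percentile and threshold defaults
#' match the settings used for automated endosome detection (percentile
#' low 25, high 99.8, probability threshold 0.5, overlap threshold 0); the
#' blob radius range covers diffraction-limited endo/lysosomes at 133 nm
#' pixels.
#'
#' @param percentile_low,percentile_high Normalisation percentiles.
#' @param prob_threshold Detection probability threshold in `[0, 1]`.
#' @param overlap_threshold Allowed overlap between candidate objects; 0
#'   (the only supported value for the classical backend) resolves
#'   candidates exclusively, no shared pixels.
#' @param backend `"classical"` (multi-scale blob detector) or
#'   `"external-model"` (adopt a label image from an external star-convex
#'   detector, supplied via `external_labels`).
#' @param radii_px Blob radii (pixels) enhanced by the classical detector.
#' @param external_labels Integer label matrix for the external backend.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(percentile_low = 25, percentile_high = 99.8,
                                prob_threshold = 0.5, overlap_threshold = 0,
                                backend = c("classical", "external-model"),
                                radii_px = c(2, 2.8, 4, 5.7, 8),
                                external_labels = NULL) {
  backend <- match.arg(backend)
  if (!(percentile_low >= 0 && percentile_low < percentile_high && percentile_high <= 100))
    abort("need 0 <= percentile_low < percentile_high <= 100.")
  if (prob_threshold < 0 || prob_threshold > 1)
    abort("`prob_threshold` must be in [0, 1].")
  structure(list(percentile_low = percentile_low, percentile_high = percentile_high,
                 prob_threshold = prob_threshold, overlap_threshold = overlap_threshold,
                 backend = backend, radii_px = radii_px,
                 external_labels = external_labels),
            class = "segmentation_params")
}

log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- (-half):half
  g <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g <- g / sum(g)
  r2 <- outer(ax, ax, function(x, y) x^2 + y^2)
  k <- g * (r2 - 2 * sigma^2) / sigma^4
  k - mean(k)  # zero-sum so flat regions respond 0
}

#' Detect endo/lysosome-like objects in an intensity image
#'
#' The classical backend percentile-normalises the image, enhances blobs
#' with a scale-normalised multi-scale Laplacian-of-Gaussian filter over
#' `radii_px`, partitions the above-noise response into watershed basins
#' (touching blobs split along the response valley, so candidates never
#' share pixels — the `overlap_threshold = 0` semantics), scores each
#' basin with a detection-probability proxy from its peak response
#' (`1 - exp(-log(2) * peak / (5 * sigma_bg))`, so a peak 5 background SDs
#' above the LoG noise floor scores 0.5), and keeps basins scoring at
#' least `prob_threshold`. The `"external-model"` backend adopts a label image
#' produced by any external star-convex detector (e.g. a trained deep
#' segmentation network) so every downstream quantity is available either
#' way. Detection is deterministic given the image and parameters.
#'
#' @param img Numeric intensity matrix (photon counts).
#' @param params A [segmentation_params()].
#' @return A [label_mask()]; empty or constant images yield a 0-label mask
#'   with a warning.
#' @param pixel_size Pixel size in micrometres (default 0.133).
#' @export
detect_vesicles <- function(img, params = segmentation_params(),
                            pixel_size = 0.133) {
  stopifnot(is.matrix(img), inherits(params, "segmentation_params"))
  if (params$backend == "external-model") {
    if (is.null(params$external_labels))
      abort("backend 'external-model' needs `external_labels` in the parameter set.")
    return(label_mask(params$external_labels, pixel_size))
  }
  empty <- label_mask(matrix(0L, nrow(img), ncol(img)), pixel_size)
  norm <- tryCatch(
    normalize_percentiles(img, params$percentile_low, params$percentile_high),
    error = function(e) NULL)
  if (is.null(norm)) {
    warn("detect_vesicles: constant or empty image, returning an empty mask.")
    return(empty)
  }
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (r in params$radii_px) {
    sigma <- r / sqrt(2)
    k <- log_kernel(sigma)
    if (nrow(k) > nrow(img) || ncol(k) > ncol(img)) next  # scale larger than image
    resp_s <- -sigma^2 * filter2_mat(norm, k)
    resp <- pmax(resp, resp_s)
  }
  if (!any(is.finite(resp))) {
    warn("detect_vesicles: image smaller than every detection scale, returning an empty mask.")
    return(empty)
  }
  # noise floor from the negative response tail: blob responses are strictly
  # positive, so the negative side is uncontaminated background noise
  neg <- resp[resp < 0]
  sigma_bg <- if (length(neg) > 100) median(abs(neg)) / qnorm(0.75)
              else mad(resp, center = 0)
  if (!is.finite(sigma_bg) || sigma_bg <= 0) sigma_bg <- sd(resp)
  if (!is.finite(sigma_bg) || sigma_bg <= 0) {
    warn("detect_vesicles: no blob response above noise, returning an empty mask.")
    return(empty)
  }
  # candidate objects: watershed basins of the response topography over the
  # above-noise support; touching blobs split along the response valley, so
  # candidates never share pixels (overlap_threshold = 0 semantics)
  support <- resp > 2 * sigma_bg
  if (!any(support)) {
    warn("detect_vesicles: no response above the noise floor, returning an empty mask.")
    return(empty)
  }
  hm <- resp; hm[!support] <- 0
  basins <- as.matrix(EBImage::watershed(EBImage::Image(hm),
                                         tolerance = 5 * sigma_bg, ext = 1))
  # per-basin detection probability from its peak response: a peak 5
  # background SDs above the LoG noise floor scores 0.5
  peak <- tapply(resp[basins > 0], basins[basins > 0], max)
  prob <- 1 - exp(-log(2) * pmax(peak, 0) / (5 * sigma_bg))
  keep <- as.integer(names(peak))[prob >= params$prob_threshold]
  if (length(keep) == 0L) {
    warn("detect_vesicles: no candidate passed the probability threshold, returning an empty mask.")
    return(empty)
  }
  basins[!(basins %in% keep)] <- 0L
  label_mask(basins, pixel_size)
}

filter2_mat <- function(x, k) {
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Post-filter a label mask by area and per-pixel intensity
#'
#' Applies the label post-filters used after automated detection: pixels
#' below the photon threshold are removed from every region first, then
#' regions whose remaining pixel area exceeds `max_area_um2` (2 um^2 by
#' default; at 133 nm pixels that is ~113 px) are discarded. Surviving
#' labels are recompacted to 1..K.
#'
#' @param mask A [label_mask()].
#' @param photons Photon-count matrix congruent with the mask.
#' @param max_area_um2 Upper area cutoff in um^2 (default 2).
#' @param min_photons Per-pixel photon threshold (default 15).
#' @return A filtered [label_mask()].
#' @export
filter_labels <- function(mask, photons, max_area_um2 = 2, min_photons = 15) {
  stopifnot(inherits(mask, "label_mask"))
  if (!all(dim(photons) == dim(mask$labels)))
    abort("`photons` grid must be congruent with the mask.")
  lab <- mask$labels
  lab[photons < min_photons] <- 0L
  if (is.finite(max_area_um2)) {
    cutoff <- max_area_um2 / mask$pixel_size^2
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas > cutoff)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  label_mask(lab, mask$pixel_size)
}

#' Erode every region of a label mask label-wise
#'
#' Binary erosion with a 3x3 structuring element applied per label: a pixel
#' survives only if its full 3x3 neighbourhood carries the same label, so
#' distinct regions can never merge and nearby-but-separate vesicles stay
#' resolved. Regions eroded to extinction are dropped; survivors are
#' recompacted.
#'
#' @param mask A [label_mask()].
#' @param iterations Number of erosion passes (default 1; 0 is the
#'   identity).
#' @return The eroded [label_mask()].
#' @export
erode_labels <- function(mask, iterations = 1) {
  stopifnot(inherits(mask, "label_mask"))
  if (iterations < 0) abort("`iterations` must be >= 0.")
  lab <- mask$labels
  for (i in seq_len(iterations)) {
    h <- nrow(lab); w <- ncol(lab)
    p <- matrix(-1L, h + 2, w + 2)     # pad with a sentinel != any label
    p[2:(h + 1), 2:(w + 1)] <- lab
    keep <- lab > 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      keep <- keep & (p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)] == lab)
    }
    lab[!keep] <- 0L
  }
  label_mask(lab, mask$pixel_size)
}

#' Double-positive and single-positive masks across two channels
#'
#' Classifies the regions of `mask_a` (e.g. mApple vesicles, original
#' non-eroded extents) by whether at least one of their pixels overlaps any
#' region of `mask_b` (the partner channel, supplied already eroded by one
#' pixel so near-misses do not count). Returns the double-positive regions
#' with their original extents and the complementary A-only mask.
#'
#' @param mask_a,mask_b Congruent [label_mask()] objects; `mask_b` should
#'   already be eroded (see [erode_labels()]).
#' @return List with `dp` and `a_only` label masks; each carries an
#'   attribute `source_label` mapping its compact labels back to `mask_a`
#'   labels.
#' @export
double_positive_mask <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "label_mask"), inherits(mask_b, "label_mask"))
  if (!all(dim(mask_a$labels) == dim(mask_b$labels)))
    abort("mask grids differ in shape.")
  a <- mask_a$labels
  overlap <- unique(a[a > 0L & mask_b$labels > 0L])
  all_ids <- sort(unique(a[a > 0L]))
  dp_lab <- a; dp_lab[!(a %in% overlap)] <- 0L
  ao_lab <- a; ao_lab[a %in% overlap] <- 0L
  dp <- label_mask(dp_lab, mask_a$pixel_size)
  ao <- label_mask(ao_lab, mask_a$pixel_size)
  attr(dp, "source_label") <- sort(intersect(all_ids, overlap))
  attr(ao, "source_label") <- sort(setdiff(all_ids, overlap))
  list(dp = dp, a_only = ao)
}

#' Coincidence percentage between two channels
#'
#' Percentage of A-channel vesicles that are double-positive:
#' `100 * n(dp) / n(all_a)`. Returns 0 with a warning when no A vesicles
#' were detected.
#'
#' @param dp Double-positive [label_mask()] (subset of `all_a`).
#' @param all_a All A-channel vesicles.
#' @return Numeric percentage.
#' @export
coincidence_percent <- function(dp, all_a) {
  stopifnot(inherits(dp, "label_mask"), inherits(all_a, "label_mask"))
  n_all <- n_labels(all_a)
  if (n_all == 0L) {
    warn("coincidence_percent: no vesicles in the reference mask; returning 0.")
    return(0)
  }
  100 * n_labels(dp) / n_all
}
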