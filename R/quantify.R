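#' Photon-weighted G value per vesicle
#'
#' The per-vesicle analogue of [image_weighted_G()]: for each labelled
#' region,
#' \deqn{\bar G_k = \frac{\sum_{xy \in k} P_{xy} G_{xy}}{\sum_{xy \in k} P_{xy}},}
#' summing over the region's valid pixels only. Weighting by photon count
#' pulls the estimate toward the best-measured pixels. Regions whose valid
#' pixels carry no photons are dropped with a warning.
#'
#' @param phasor A `phasor_image`.
#' @param mask A [label_mask()] congruent with it.
#' @return Tibble with `label`, `weighted_g`, `total_photons`.
#' @export
vesicle_weighted_G <- function(phasor, mask) {
  stopifnot(inherits(phasor, "phasor_image"), inherits(mask, "label_mask"))
  if (!all(dim(phasor$G) == dim(mask$labels)))
    abort("phasor and mask grids differ in shape.")
  lab <- mask$labels
  use <- lab > 0L & phasor$valid
  all_ids <- sort(unique(lab[lab > 0L]))
  if (!any(use)) {
    if (length(all_ids)) warn("all regions dropped: no valid pixels with photons.")
    return(tibble(label = integer(), weighted_g = double(), total_photons = double()))
  }
  lk <- lab[use]
  wsum <- tapply(as.numeric(phasor$photons[use]), lk, sum)
  gsum <- tapply(as.numeric(phasor$photons[use]) * phasor$G[use], lk, sum)
  ids <- as.integer(names(wsum))
  keep <- wsum > 0
  dropped <- union(setdiff(all_ids, ids), ids[!keep])
  if (length(dropped))
    warn(sprintf("dropping %d region(s) with zero valid-pixel photons: %s",
                 length(dropped), paste(head(dropped, 10), collapse = ", ")))
  tibble(label = ids[keep],
         weighted_g = as.numeric(gsum[keep] / wsum[keep]),
         total_photons = as.numeric(wsum[keep]))
}

#' Per-vesicle quantification table
#'
#' The central per-object analysis: for every labelled vesicle, the
#' photon-weighted G value, its conversion to pH through the supplied
#' calibration, the SD of per-pixel pH inside the region (intra-vesicle
#' heterogeneity), geometry, and summed intensities of any auxiliary cargo
#' channels over the region's original extent.
#'
#' @param phasor A `phasor_image` (already photon-thresholded as desired).
#' @param mask A [label_mask()].
#' @param cal A [fit_g_calibration()] result (default the reference line).
#' @param aux Named list of intensity matrices (e.g. `list(cy5 = ...)`);
#'   summed per region as `aux_<name>` columns.
#' @param allow_extrapolation Convert weighted G values outside the
#'   calibrated range? Default TRUE — shot noise legitimately pushes
#'   measured G slightly past the anchors; such rows are flagged in the
#'   `extrapolated` column rather than erroring.
#' @return Tibble with one row per vesicle: `label`, `area_px`, `area_um2`,
#'   `total_photons`, `weighted_g`, `ph`, `ph_sd`, `centroid_row`,
#'   `centroid_col` (0-based), `extrapolated`, and `aux_*` columns.
#' @export
vesicle_table <- function(phasor, mask, cal = default_g_calibration(),
                          aux = list(), allow_extrapolation = TRUE) {
  stopifnot(inherits(cal, "g_calibration"))
  wg <- vesicle_weighted_G(phasor, mask)
  geom <- label_table(mask)
  out <- dplyr::inner_join(geom, wg, by = "label")
  if (nrow(out) == 0L) {
    out$weighted_g <- double(); out$total_photons <- double()
    out$ph <- double(); out$ph_sd <- double(); out$extrapolated <- logical()
    return(out)
  }
  conv <- g_to_ph(out$weighted_g, cal, allow_extrapolation = allow_extrapolation)
  out$ph <- conv$ph
  out$extrapolated <- out$weighted_g < cal$g_range[1] | out$weighted_g > cal$g_range[2]
  # intra-vesicle SD of per-pixel pH (same calibration, no re-thresholding)
  lab <- mask$labels
  use <- lab > 0L & phasor$valid & lab %in% out$label
  px_ph <- cal$intercept + cal$slope * phasor$G[use]
  sd_tab <- tapply(px_ph, lab[use], sd)
  out$ph_sd <- as.numeric(sd_tab[as.character(out$label)])
  out$ph_sd[is.na(out$ph_sd)] <- 0  # single-pixel regions
  for (nm in names(aux)) {
    img <- aux[[nm]]
    if (!all(dim(img) == dim(lab))) abort(sprintf("aux channel '%s' grid mismatch.", nm))
    sums <- tapply(as.numeric(img[lab > 0L]), lab[lab > 0L], sum)
    out[[paste0("aux_", nm)]] <- as.numeric(sums[as.character(out$label)])
  }
  dplyr::relocate(out, "label", "area_px", "area_um2", "total_photons",
                  "weighted_g", "ph", "ph_sd", "centroid_row", "centroid_col",
                  "extrapolated")
}

#' Analyse a (simulated or loaded) scene end-to-end in memory
#'
#' Convenience wrapper chaining the standard analysis: per-pixel phasor,
#' photon threshold, vesicle detection on the photon image, area
#' post-filter, and per-vesicle quantification. Equivalent to
#' [run_pipeline()] without touching disk.
#'
#' @param scene A `flim_scene` from [simulate_cell_scene()], or a
#'   [decay_image()].
#' @param cal Calibration for the G-to-pH conversion.
#' @param min_photons Photon threshold (default 15).
#' @param max_area_um2 Area cutoff (default 2).
#' @param params [segmentation_params()] for detection.
#' @param use_truth_mask Quantify over the scene's ground-truth mask instead
#'   of detecting (only for `flim_scene` input; default FALSE).
#' @return List with `phasor`, `mask`, `vesicles` (tibble), `summary`
#'   (tibble).
#' @export
analyze_scene <- function(scene, cal = default_g_calibration(),
                          min_photons = 15, max_area_um2 = 2,
                          params = segmentation_params(),
                          use_truth_mask = FALSE) {
  decay <- if (inherits(scene, "flim_scene")) scene$decay else scene
  stopifnot(inherits(decay, "decay_image"))
  phasor <- threshold_photons(compute_phasor(decay), min_photons)
  mask <- if (use_truth_mask && inherits(scene, "flim_scene")) {
    scene$truth_mask
  } else {
    filter_labels(detect_vesicles(phasor$photons, params,
                                  pixel_size = decay$pixel_size),
                  phasor$photons, max_area_um2, min_photons)
  }
  aux <- if (inherits(scene, "flim_scene")) scene$aux else list()
  vesicles <- vesicle_table(phasor, mask, cal, aux = aux)
  list(phasor = phasor, mask = mask, vesicles = vesicles,
       summary = if (nrow(vesicles)) summarize_image(vesicles) else NULL)
}

#' Summarise a vesicle table into image-level statistics
#'
#' Mean pH (unweighted over vesicles, so every vesicle is one observation —
#' a photon-weighted mean is available via `weighted = TRUE`), modal pH
#' (binned, ties toward lower pH), and the "majority interval": the 0.125
#' and 0.875 quantiles (middle 75%) of vesicle pH, computed with the
#' linear-interpolation quantile convention.
#'
#' @param records A [vesicle_table()] tibble (needs `ph`; `total_photons`
#'   for the weighted variant).
#' @param mode_bin Histogram bin width for the modal pH (default 0.1).
#' @param weighted Weight the mean by per-vesicle photon counts?
#' @param timepoint,condition Optional annotations carried into the output.
#' @return One-row tibble: `mean_ph`, `modal_ph`, `majority_low`,
#'   `majority_high`, `n_vesicles` (+ annotations).
#' @export
summarize_image <- function(records, mode_bin = 0.1, weighted = FALSE,
                            timepoint = NA_real_, condition = NA_character_) {
  if (nrow(records) == 0L) abort("empty vesicle table: nothing to summarise.")
  ph <- records$ph
  mean_ph <- if (weighted) {
    sum(ph * records$total_photons) / sum(records$total_photons)
  } else mean(ph)
  idx <- floor(ph / mode_bin + 1e-9)
  mass <- table(idx)
  centres <- (as.numeric(names(mass)) + 0.5) * mode_bin
  best <- which(mass == max(mass))
  modal_ph <- centres[best[which.min(centres[best])]]
  q <- quantile(ph, c(0.125, 0.875), names = FALSE, type = 7)
  tibble(mean_ph = mean_ph, modal_ph = modal_ph,
         majority_low = q[1], majority_high = q[2],
         n_vesicles = nrow(records),
         timepoint = timepoint, condition = condition)
}

#' Compare two treatment arms per timepoint
#'
#' Classic equal-variance two-sample t-test on replicate-level mean pH at
#' each timepoint, the per-timepoint comparison used for drug time courses.
#' Degenerate (zero-variance) timepoints are handled explicitly: identical
#' groups give t = 0, p = 1.
#'
#' @param summaries_a,summaries_b Data frames of replicate image summaries
#'   with columns `timepoint` and `mean_ph` (>= 2 replicates per arm per
#'   timepoint).
#' @return Tibble per shared timepoint: `timepoint`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `t_stat`, `p_value`.
#' @export
timecourse_compare <- function(summaries_a, summaries_b) {
  a <- as.data.frame(summaries_a); b <- as.data.frame(summaries_b)
  for (d in list(a, b))
    if (!all(c("timepoint", "mean_ph") %in% names(d)))
      abort("summaries need columns `timepoint` and `mean_ph`.")
  tps <- sort(intersect(unique(a$timepoint), unique(b$timepoint)))
  if (length(tps) == 0L) abort("no shared timepoints between the two arms.")
  purrr::map_dfr(tps, function(tp) {
    xa <- a$mean_ph[a$timepoint == tp]
    xb <- b$mean_ph[b$timepoint == tp]
    if (length(xa) < 2L || length(xb) < 2L)
      abort(sprintf("timepoint %s has fewer than 2 replicates in one arm.", format(tp)))
    res <- tryCatch(
      t.test(xa, xb, var.equal = TRUE),
      error = function(e) {
        # pooled variance is zero
        if (mean(xa) == mean(xb)) list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(xa) - mean(xb)) * Inf, p.value = 0)
      })
    tibble(timepoint = tp, mean_a = mean(xa), mean_b = mean(xb),
           n_a = length(xa), n_b = length(xb),
           t_stat = unname(res$statistic), p_value = unname(res$p.value))
  })
}

#' Correlation between cargo load and vesicle pH
#'
#' Tests whether vesicles carrying more cargo (e.g. Cy5-labelled polymer)
#' sit at different pH — the read-out for buffering ("proton sponge")
#' hypotheses. Both Pearson's r and Spearman's rho are reported.
#'
#' @param records A [vesicle_table()] with an `aux_<channel>` column.
#' @param channel Auxiliary channel name (e.g. `"cy5"`).
#' @return A `cargo_correlation`: list with `pairs` (tibble `intensity`,
#'   `ph`), `pearson_r`, `spearman_rho`, `n`; correlations are NA with a
#'   warning when the intensity is constant.
#' @export
cargo_ph_correlation <- function(records, channel = "cy5") {
  colnm <- paste0("aux_", channel)
  if (!colnm %in% names(records))
    abort(sprintf("records carry no `%s` column: was the aux channel quantified?", colnm))
  pairs <- tibble(intensity = records[[colnm]], ph = records$ph)
  pairs <- pairs[complete.cases(pairs), ]
  if (nrow(pairs) < 3L) abort("need at least 3 vesicles to correlate cargo load with pH.")
  if (sd(pairs$intensity) == 0 || sd(pairs$ph) == 0) {
    warn("cargo_ph_correlation: constant intensity or pH, correlation undefined.")
    r <- NA_real_; rho <- NA_real_
  } else {
    r <- cor(pairs$intensity, pairs$ph, method = "pearson")
    rho <- cor(pairs$intensity, pairs$ph, method = "spearman")
  }
  structure(list(pairs = pairs, pearson_r = r, spearman_rho = rho,
                 n = nrow(pairs), channel = channel),
            class = "cargo_correlation")
}

#' @export
print.cargo_correlation <- function(x, ...) {
  cat(sprintf("<cargo_correlation> %s vs pH over %d vesicles: Pearson r = %.3f, Spearman rho = %.3f\n",
              x$channel, x$n, x$pearson_r, x$spearman_rho))
  invisible(x)
}

#' @rdname phlimr-tidiers
#' @export
tidy.cargo_correlation <- function(x, ...) {
  tibble(channel = x$channel, n = x$n,
         pearson_r = x$pearson_r, spearman_rho = x$spearman_rho)
}
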