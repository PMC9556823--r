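# ggplot2 figure helpers. The fixed pH pseudo-colour ("phasor mask") maps
# G in [0.35, 0.70] onto a red (neutral) -> blue (acidic) gradient.

ph_mask_colours <- function() {
  list(limits = c(0.35, 0.70),
       colours = c("#d73027", "#fc8d59", "#fee090", "#e0f3f8", "#91bfdb", "#4575b4"))
}

#' Phasor-plot density of an image
#'
#' 2-D photon-weighted histogram of per-pixel (G, S) with the universal
#' semicircle overlaid: single-exponential decays fall on the arc, mixtures
#' inside it.
#'
#' @param object A `phasor_image`.
#' @param bins Number of hexagonal bins (default 80).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phasor_image <- function(object, bins = 80, ...) {
  df <- tibble(g = object$G[object$valid], s = object$S[object$valid],
               photons = as.numeric(object$photons[object$valid]))
  semi <- tibble(g = 0.5 + 0.5 * cos(seq(0, pi, length.out = 181)),
                 s = 0.5 * sin(seq(0, pi, length.out = 181)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_bin2d(ggplot2::aes(weight = .data$photons), bins = bins) +
    ggplot2::geom_path(data = semi, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "photons") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "G", y = "S", title = "Phasor plot") +
    ggplot2::theme_minimal()
}

#' Calibration plots
#'
#' For a linear G calibration: points, fitted line and the 95% prediction
#' band. For a 4PL intensity calibration: normalised points and the fitted
#' logistic.
#'
#' @param object A fitted calibration.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g_calibration <- function(object, ...) {
  gg <- seq(object$g_range[1], object$g_range[2], length.out = 101)
  band <- g_to_ph(gg, object)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$g, y = .data$ph)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ph - .data$half_width_95,
                                      ymax = .data$ph + .data$half_width_95),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data, ggplot2::aes(x = .data$g, y = .data$ph)) +
    ggplot2::labs(x = "G value", y = "pH", title = "G value calibration") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.g_calibration
#' @export
autoplot.intensity_calibration <- function(object, ...) {
  ph <- seq(object$ph_range[1], object$ph_range[2], length.out = 151)
  fit <- tibble(ph = ph, norm = predict(object, ph))
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$ph, y = .data$norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data, ggplot2::aes(y = .data$norm)) +
    ggplot2::labs(x = "pH", y = "normalised intensity",
                  title = "Intensity calibration (4PL)") +
    ggplot2::theme_minimal()
}

#' Vesicle pH histogram
#'
#' The standard per-image read-out: pH of every detected vesicle, the mean
#' as a dotted line.
#'
#' @param records A [vesicle_table()] tibble.
#' @param binwidth pH bin width (default 0.1).
#' @return A ggplot.
#' @export
plot_ph_histogram <- function(records, binwidth = 0.1) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ph)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#4575b4", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(records$ph), linetype = 3) +
    ggplot2::labs(x = "vesicle pH", y = "vesicles") +
    ggplot2::theme_minimal()
}

#' pH-coloured vesicle mask image
#'
#' Renders detected vesicles coloured by their weighted-G pseudo-colour
#' scale (fixed over G 0.35-0.70) on a dark background — the per-object
#' version of the phasor-mask overlay.
#'
#' @param phasor A `phasor_image`.
#' @param mask A [label_mask()].
#' @param cal Calibration used for the pH legend (default reference line).
#' @return A ggplot.
#' @export
plot_ph_mask <- function(phasor, mask, cal = default_g_calibration()) {
  vt <- vesicle_table(phasor, mask, cal)
  lab <- mask$labels
  keep <- lab > 0L & lab %in% vt$label
  df <- tibble(row = row(lab)[keep] - 1, col = col(lab)[keep] - 1,
               g = vt$weighted_g[match(lab[keep], vt$label)])
  pal <- ph_mask_colours()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$g)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = rev(pal$colours), limits = pal$limits,
                                  oob = scales_squish, name = "weighted G") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "black"))
}

# minimal squish (avoids a scales dependency): clamp out-of-bounds to limits
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Time-course summary plot
#'
#' Mean vesicle pH per replicate over time for two arms, with per-arm mean
#' lines.
#'
#' @param summaries_a,summaries_b Replicate summaries (columns `timepoint`,
#'   `mean_ph`).
#' @param labels Arm names (length 2).
#' @return A ggplot.
#' @export
plot_timecourse <- function(summaries_a, summaries_b,
                            labels = c("treated", "untreated")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(summaries_a), condition = labels[1]),
    dplyr::mutate(as_tibble(summaries_b), condition = labels[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mean_ph,
                                   colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "time (min)", y = "mean vesicle pH", colour = NULL) +
    ggplot2::theme_minimal()
}
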