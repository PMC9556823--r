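#' Fit the linear G-to-pH calibration
#'
#' Ordinary least squares of pH on the phasor G coordinate. The mApple G
#' value rises linearly as pH falls across the physiological range, so a
#' straight line converts measured G directly to pH. The fit state needed
#' for 95% prediction bands (residual SD, mean G, sum of squares) is stored
#' so [g_to_ph()] can report per-conversion uncertainty.
#'
#' @param pairs A data frame with numeric columns `g` and `ph` (one row per
#'   calibration measurement; upper-case `G`/`pH` column names are accepted).
#' @param conf Band confidence level (default 0.95).
#' @return A `g_calibration` object with fields `slope` (pH per G unit),
#'   `intercept` (pH at G = 0), `n`, `x_mean`, `s_xx`, `resid_sd`, `conf`,
#'   `g_range`.
#' @examples
#' cal <- fit_g_calibration(data.frame(
#'   g = c(0.39, 0.45, 0.52, 0.57, 0.62), ph = c(7.4, 6.8, 6.1, 5.6, 5.1)))
#' tidy(cal)
#' g_to_ph(0.60, cal)
#' @seealso [g_to_ph()], [ph_to_g()], [default_g_calibration()]
#' @export
fit_g_calibration <- function(pairs, conf = 0.95) {
  pairs <- normalize_cal_cols(pairs, value_col = "g")
  if (nrow(pairs) < 2L) abort("need at least 2 calibration pairs.")
  if (anyNA(pairs$g) || anyNA(pairs$ph)) abort("calibration pairs contain NA.")
  if (length(unique(pairs$g)) < 2L)
    abort("all G values are identical: the calibration line is undefined.")
  if (conf <= 0 || conf >= 1) abort("`conf` must be in (0, 1).")
  fit <- lm(ph ~ g, data = pairs)
  n <- nrow(pairs)
  res <- sum(residuals(fit)^2)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    n = n, x_mean = mean(pairs$g), s_xx = sum((pairs$g - mean(pairs$g))^2),
    resid_sd = if (n > 2) sqrt(res / (n - 2)) else 0,
    conf = conf, g_range = range(pairs$g), data = as_tibble(pairs)),
    class = "g_calibration")
}

normalize_cal_cols <- function(pairs, value_col) {
  pairs <- as.data.frame(pairs)
  nm <- tolower(names(pairs))
  names(pairs)[nm == "ph"] <- "ph"
  names(pairs)[nm == value_col] <- value_col
  if (value_col == "intensity" && !"intensity" %in% names(pairs) && "value" %in% nm)
    names(pairs)[nm == "value"] <- "intensity"
  if (value_col == "g" && !"g" %in% names(pairs) && "value" %in% nm)
    names(pairs)[nm == "value"] <- "g"
  need <- c("ph", value_col)
  if (!all(need %in% names(pairs)))
    abort(sprintf("`pairs` must have columns %s.", paste0("`", need, "`", collapse = " and ")))
  pairs[need]
}

#' @export
print.g_calibration <- function(x, ...) {
  cat(sprintf("<g_calibration> pH = %.4g %+.4g * G  (n = %d, resid SD = %.3g pH, G in [%.3g, %.3g])\n",
              x$intercept, x$slope, x$n, x$resid_sd, x$g_range[1], x$g_range[2]))
  invisible(x)
}

# t critical value at the calibration's residual degrees of freedom
cal_t_crit <- function(cal) {
  df <- if (inherits(cal, "intensity_calibration")) cal$n - 4 else cal$n - 2
  if (df < 1) abort("prediction bands need more calibration points than parameters.")
  qt(1 - (1 - cal$conf) / 2, df)
}

#' Convert G values to pH with prediction-band uncertainty
#'
#' Evaluates the fitted calibration line at `g` and reports the half-width
#' of the 95% prediction band there, i.e. the pH uncertainty of a single new
#' measurement:
#' \deqn{\mathrm{hw}(g) = t_{1-\alpha/2,\,n-2}\; s\;
#'   \sqrt{1 + 1/n + (g - \bar g)^2 / S_{gg}}.}
#'
#' @param g Numeric vector of measured G values.
#' @param cal A [fit_g_calibration()] result.
#' @param allow_extrapolation Evaluate outside the calibrated G range? Off by
#'   default; extrapolated conversions error unless enabled.
#' @return A tibble with columns `g`, `ph`, `half_width_95` (NA when `n < 3`).
#' @export
g_to_ph <- function(g, cal, allow_extrapolation = FALSE) {
  stopifnot(inherits(cal, "g_calibration"))
  out_of_range <- g < cal$g_range[1] | g > cal$g_range[2]
  if (!allow_extrapolation && any(out_of_range))
    abort(sprintf(
      "G value(s) %s outside the calibrated range [%.3g, %.3g]; set `allow_extrapolation = TRUE` to override.",
      paste(signif(g[out_of_range], 3), collapse = ", "),
      cal$g_range[1], cal$g_range[2]))
  ph <- cal$intercept + cal$slope * g
  hw <- if (cal$n > 2)
    cal_t_crit(cal) * cal$resid_sd * sqrt(1 + 1 / cal$n + (g - cal$x_mean)^2 / cal$s_xx)
  else NA_real_
  tibble(g = g, ph = ph, half_width_95 = hw)
}

#' Forward map: pH to expected G
#'
#' Inverse of the fitted calibration line; the simulator's forward model for
#' the expected phasor G coordinate at a given pH. Round-trips with
#' [g_to_ph()] to machine precision.
#'
#' @param ph Numeric vector of pH values.
#' @param cal A [fit_g_calibration()] result.
#' @return Numeric vector of G values.
#' @export
ph_to_g <- function(ph, cal) {
  stopifnot(inherits(cal, "g_calibration"))
  if (cal$slope == 0) abort("calibration slope is zero: pH does not determine G.")
  (ph - cal$intercept) / cal$slope
}

#' Reference G-to-pH calibration line
#'
#' The calibration line through the five image-level (G, pH) anchor pairs of
#' the mApple sensor — (0.39, 7.4), (0.45, 6.8), (0.52, 6.1), (0.57, 5.6),
#' (0.62, 5.1) — which are exactly collinear: pH = 11.3 - 10 G. Used as the
#' default conversion wherever no user calibration is supplied.
#'
#' @return A `g_calibration`.
#' @export
default_g_calibration <- function() {
  fit_g_calibration(tibble(g = c(0.39, 0.45, 0.52, 0.57, 0.62),
                           ph = c(7.4, 6.8, 6.1, 5.6, 5.1)))
}

# ---- four-parameter logistic intensity calibration ----------------------

logistic4 <- function(ph, bottom, top, midpoint, hill) {
  bottom + (top - bottom) / (1 + 10^((midpoint - ph) * hill))
}

#' Fit the 4PL intensity-to-pH calibration
#'
#' Intensity-based pH readout for comparison with the lifetime readout.
#' Emission intensities are normalised to the value at the highest
#' (most neutral) calibration pH and fitted with a four-parameter logistic
#' in pH (base-10 dose-response convention):
#' \deqn{I(\mathrm{pH}) = b + \frac{t - b}{1 + 10^{(m - \mathrm{pH})\,h}}.}
#'
#' @param pairs Data frame with numeric columns `ph` and `intensity`
#'   (a `value` column is accepted as the intensity).
#' @param conf Confidence level for uncertainty reporting (default 0.95).
#' @return An `intensity_calibration` with the fitted `bottom`, `top`,
#'   `midpoint`, `hill`, the normalisation anchor `anchor_ph`, parameter
#'   covariance `fit_cov`, `resid_sd`, `n`, and the calibrated `ph_range`.
#' @examples
#' ph <- seq(4.6, 7.4, by = 0.4)
#' cal <- fit_intensity_calibration(data.frame(
#'   ph = ph, intensity = 0.07 + 0.93 / (1 + 10^(6 - ph))))
#' glance(cal)
#' @export
fit_intensity_calibration <- function(pairs, conf = 0.95) {
  pairs <- normalize_cal_cols(pairs, value_col = "intensity")
  if (nrow(pairs) < 5L) abort("need at least 5 (pH, intensity) points spanning the transition.")
  if (anyNA(pairs$ph) || anyNA(pairs$intensity)) abort("calibration pairs contain NA.")
  anchor_ph <- max(pairs$ph)
  anchor <- mean(pairs$intensity[pairs$ph == anchor_ph])
  if (anchor <= 0) abort("intensity at the anchor pH must be positive for normalisation.")
  pairs$norm <- pairs$intensity / anchor
  if (diff(range(pairs$norm)) < 1e-6)
    abort("intensity does not vary with pH: the 4PL fit is degenerate (flat data).")
  start <- list(bottom = min(pairs$norm), top = max(pairs$norm),
                midpoint = mean(range(pairs$ph)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(norm ~ logistic4(ph, bottom, top, midpoint, hill),
                      data = pairs, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(sprintf(
      "4PL intensity fit did not converge: %s (starts: bottom=%.3g top=%.3g midpoint=%.3g hill=1)",
      conditionMessage(e), start$bottom, start$top, start$midpoint)))
  p <- coef(fit)
  if (p[["top"]] <= p[["bottom"]])
    abort("4PL fit inverted (top <= bottom): intensity must fall toward acidic pH.")
  if (abs(p[["hill"]]) < 1e-3)
    abort("4PL fit degenerate: hill slope ~ 0 (flat response).")
  structure(list(
    bottom = unname(p["bottom"]), top = unname(p["top"]),
    midpoint = unname(p["midpoint"]), hill = unname(p["hill"]),
    anchor_ph = anchor_ph, fit_cov = vcov(fit),
    resid_sd = summary(fit)$sigma, n = nrow(pairs),
    conf = conf, ph_range = range(pairs$ph), data = as_tibble(pairs)),
    class = "intensity_calibration")
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat(sprintf(
    "<intensity_calibration> 4PL: bottom %.3g, top %.3g, midpoint pH %.3g, hill %.3g (n = %d, resid SD %.3g)\n",
    x$bottom, x$top, x$midpoint, x$hill, x$n, x$resid_sd))
  invisible(x)
}

#' Predict normalised intensity from pH under a 4PL calibration
#'
#' @param object An `intensity_calibration`.
#' @param ph Numeric vector of pH values.
#' @param ... Unused.
#' @return Numeric vector of predicted normalised intensities.
#' @export
predict.intensity_calibration <- function(object, ph, ...) {
  logistic4(ph, object$bottom, object$top, object$midpoint, object$hill)
}

intensity_pred_se <- function(cal, ph) {
  # prediction SE: residual noise + parameter uncertainty (delta method)
  b <- cal$bottom; t_ <- cal$top; m <- cal$midpoint; h <- cal$hill
  den <- 1 + 10^((m - ph) * h)
  frac <- 1 / den
  dtop <- frac
  dbottom <- 1 - frac
  core <- (t_ - b) * (10^((m - ph) * h) * log(10)) / den^2
  dmid <- -core * h
  dhill <- -core * (m - ph)
  grads <- cbind(bottom = dbottom, top = dtop, midpoint = dmid, hill = dhill)
  grads <- grads[, colnames(cal$fit_cov), drop = FALSE]
  parvar <- rowSums((grads %*% cal$fit_cov) * grads)
  sqrt(cal$resid_sd^2 + pmax(parvar, 0))
}

# ---- inverse-prediction pH uncertainty ----------------------------------

#' pH uncertainty of an interpolated measurement
#'
#' Half-width (in pH units) of the interval of pH values whose predicted
#' measurement band contains the observed value — the inverse use of the 95%
#' prediction band. For the linear G calibration this is the band evaluated
#' at the measured G; for the 4PL intensity calibration the interval is
#' asymmetric (it balloons where the curve flattens at the acidic plateau)
#' and is found numerically, reported as lower/upper half-widths plus their
#' mean. This is the analysis behind comparing intensity- vs lifetime-based
#' pH readout uncertainty.
#'
#' @param cal A `g_calibration` or `intensity_calibration`.
#' @param measured Numeric vector: measured G values (linear calibration) or
#'   normalised intensities (4PL calibration).
#' @param allow_extrapolation Permit values outside the calibrated response
#'   range (default FALSE: extrapolation errors).
#' @return A tibble with columns `measured`, `ph` (point estimate),
#'   `hw_lower`, `hw_upper`, `half_width` (mean of the two).
#' @export
interpolated_ph_uncertainty <- function(cal, measured, allow_extrapolation = FALSE) {
  UseMethod("interpolated_ph_uncertainty")
}

#' @export
interpolated_ph_uncertainty.g_calibration <- function(cal, measured,
                                                      allow_extrapolation = FALSE) {
  res <- g_to_ph(measured, cal, allow_extrapolation = allow_extrapolation)
  hw <- res$half_width_95
  if (all(is.na(hw))) abort("prediction bands need at least 3 calibration points.")
  tibble(measured = measured, ph = res$ph,
         hw_lower = hw, hw_upper = hw, half_width = hw)
}

#' @export
interpolated_ph_uncertainty.intensity_calibration <- function(cal, measured,
                                                              allow_extrapolation = FALSE) {
  lo <- cal$ph_range[1]; hi <- cal$ph_range[2]
  resp_range <- range(predict(cal, c(lo, hi)))
  tcrit <- cal_t_crit(cal)
  band <- function(p) tcrit * intensity_pred_se(cal, p)
  purrr::map_dfr(measured, function(m) {
    if (!allow_extrapolation && (m < resp_range[1] || m > resp_range[2]))
      abort(sprintf(
        "measured intensity %.3g outside the calibrated response range [%.3g, %.3g] (extrapolation).",
        m, resp_range[1], resp_range[2]))
    f <- function(p) predict(cal, p) - m
    ph0 <- if (f(lo) * f(hi) <= 0) uniroot(f, c(lo, hi), tol = 1e-10)$root
           else if (abs(f(lo)) < abs(f(hi))) lo else hi
    # lower side: where does the band first exclude `m` as pH decreases?
    # If it never does (the bottom asymptote sits inside the band), the
    # measurement puts no lower bound on pH at all: the half-width is Inf.
    far <- 40 / cal$hill
    g_lo <- function(p) (m - predict(cal, p)) - band(p)
    hw_lower <- if (g_lo(ph0 - far) <= 0) Inf
                else ph0 - uniroot(g_lo, c(ph0 - far, ph0), tol = 1e-9)$root
    g_hi <- function(p) (predict(cal, p) - m) - band(p)
    hw_upper <- if (g_hi(ph0 + far) <= 0) Inf
                else uniroot(g_hi, c(ph0, ph0 + far), tol = 1e-9)$root - ph0
    tibble(measured = m, ph = ph0, hw_lower = hw_lower, hw_upper = hw_upper,
           half_width = (hw_lower + hw_upper) / 2)
  })
}
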