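#' Tidy calibration fits
#'
#' Broom-style accessors for fitted calibrations. `tidy()` returns one row
#' per parameter; `glance()` returns a one-row model summary.
#'
#' @param x A `g_calibration` or `intensity_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @name phlimr-tidiers
NULL

#' @rdname phlimr-tidiers
#' @export
tidy.g_calibration <- function(x, ...) {
  se <- if (x$n > 2) {
    c(x$resid_sd * sqrt(1 / x$n + x$x_mean^2 / x$s_xx),
      x$resid_sd / sqrt(x$s_xx))
  } else c(NA_real_, NA_real_)
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = se)
}

#' @rdname phlimr-tidiers
#' @export
glance.g_calibration <- function(x, ...) {
  ss_tot <- sum((x$data$ph - mean(x$data$ph))^2)
  ss_res <- x$resid_sd^2 * max(x$n - 2, 0)
  tibble(n = x$n, resid_sd = x$resid_sd,
         r.squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         g_min = x$g_range[1], g_max = x$g_range[2], conf = x$conf)
}

#' @rdname phlimr-tidiers
#' @export
tidy.intensity_calibration <- function(x, ...) {
  est <- c(bottom = x$bottom, top = x$top, midpoint = x$midpoint, hill = x$hill)
  se <- sqrt(pmax(diag(x$fit_cov)[names(est)], 0))
  tibble(term = names(est), estimate = unname(est), std.error = unname(se))
}

#' @rdname phlimr-tidiers
#' @export
glance.intensity_calibration <- function(x, ...) {
  tibble(n = x$n, resid_sd = x$resid_sd, anchor_ph = x$anchor_ph,
         ph_min = x$ph_range[1], ph_max = x$ph_range[2], conf = x$conf)
}

#' Fractional intensity drop between two pH values under a 4PL calibration
#'
#' Percentage drop in fitted normalised emission intensity from `ph_from`
#' (neutral) to `ph_to` (acidic): `100 * (1 - I(ph_to) / I(ph_from))`. The
#' mApple sensor loses roughly 90% of its emission between pH 7.4 and 4.6.
#'
#' @param cal An `intensity_calibration`.
#' @param ph_from,ph_to pH endpoints (defaults 7.4 and 4.6).
#' @return Numeric percentage.
#' @export
intensity_drop_percent <- function(cal, ph_from = 7.4, ph_to = 4.6) {
  stopifnot(inherits(cal, "intensity_calibration"))
  100 * (1 - predict(cal, ph_to) / predict(cal, ph_from))
}
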