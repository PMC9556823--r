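#' mApple photophysics model
#'
#' Parametric model of the pH-dependent photophysics of the mApple sensor
#' used by every simulator in the package:
#'
#' * **Phase lifetime** falls linearly with acidity, anchored at 2.2 ns
#'   (pH 7.4) and 1.3 ns (pH 4.6), about 0.32 ns per pH unit.
#' * **Phasor G coordinate** rises linearly with acidity:
#'   `G(pH) = (g0 - pH) * g_slope_inv`, anchored at G = 0.39 (pH 7.4) with
#'   slope -0.1 per pH unit, i.e. `G = (11.3 - pH)/10` — the line through
#'   the sensor's published image-level anchors.
#' * **Emission intensity** follows a four-parameter logistic in pH
#'   (bottom 0.07, top 1.0, midpoint pH 6.0, hill 1.0), normalised at
#'   pH 7.4, reproducing the ~90% intensity drop from pH 7.4 to 4.6.
#'
#' A decay realising a given pH is generated as a bi-exponential whose
#' photon-weighted phasor lands exactly on the target `(G, S)` point, with a
#' fixed short component `tau_short` and the long component determined by
#' the chord construction of [decompose_biexponential()].
#'
#' @param tau_ref,ph_ref Lifetime anchor at neutral pH (2.2 ns at pH 7.4).
#' @param tau_lo,ph_lo Lifetime anchor at acidic pH (1.3 ns at pH 4.6).
#' @param g_ref G anchor at `ph_ref` (0.39).
#' @param g_slope Slope of G per pH unit (-0.1).
#' @param intensity_4pl Named list `bottom`, `top`, `midpoint`, `hill` of the
#'   intensity logistic.
#' @param tau_short Fixed short decay component in ns (0.5).
#' @return A `photophysics_model` object.
#' @examples
#' m <- photophysics_model()
#' model_tau_phase(m, c(7.4, 4.6))
#' model_g(m, c(7.4, 5.1))
#' @export
photophysics_model <- function(tau_ref = 2.2, ph_ref = 7.4,
                               tau_lo = 1.3, ph_lo = 4.6,
                               g_ref = 0.39, g_slope = -0.1,
                               intensity_4pl = list(bottom = 0.07, top = 1.0,
                                                    midpoint = 6.0, hill = 1.0),
                               tau_short = 0.5) {
  stopifnot(tau_ref > 0, tau_lo > 0, ph_ref > ph_lo, tau_short > 0,
            intensity_4pl$top > intensity_4pl$bottom, intensity_4pl$hill > 0)
  structure(list(tau_ref = tau_ref, ph_ref = ph_ref, tau_lo = tau_lo,
                 ph_lo = ph_lo, g_ref = g_ref, g_slope = g_slope,
                 intensity_4pl = intensity_4pl, tau_short = tau_short),
            class = "photophysics_model")
}

#' @export
print.photophysics_model <- function(x, ...) {
  cat(sprintf(
    "<photophysics_model> tau %.2f ns @ pH %.1f -> %.2f ns @ pH %.1f; G(pH) = %.3f %+.3f*(pH - %.1f); 4PL midpoint pH %.2f\n",
    x$tau_ref, x$ph_ref, x$tau_lo, x$ph_lo, x$g_ref, x$g_slope, x$ph_ref,
    x$intensity_4pl$midpoint))
  invisible(x)
}

#' Evaluate the photophysics model
#'
#' `model_tau_phase()` gives the phase lifetime in ns, `model_g()` /
#' `model_s()` the target phasor coordinates (S depends on the angular
#' frequency through `S = omega * tau_phi * G`), and `model_intensity()` the
#' relative emission intensity normalised to 1 at the model's reference pH.
#'
#' @param model A [photophysics_model()].
#' @param ph Numeric vector of pH values.
#' @param omega Angular frequency in rad/ns (default first harmonic at
#'   80 MHz).
#' @return Numeric vector.
#' @export
model_tau_phase <- function(model, ph) {
  slope <- (model$tau_ref - model$tau_lo) / (model$ph_ref - model$ph_lo)
  model$tau_ref + slope * (ph - model$ph_ref)
}

#' @rdname model_tau_phase
#' @export
model_g <- function(model, ph) model$g_ref + model$g_slope * (ph - model$ph_ref)

#' @rdname model_tau_phase
#' @export
model_s <- function(model, ph, omega = 2 * pi * 0.08) {
  omega * model_tau_phase(model, ph) * model_g(model, ph)
}

#' @rdname model_tau_phase
#' @export
model_intensity <- function(model, ph) {
  p <- model$intensity_4pl
  raw <- logistic4(ph, p$bottom, p$top, p$midpoint, p$hill)
  raw / logistic4(model$ph_ref, p$bottom, p$top, p$midpoint, p$hill)
}

# phasor point of a single-exponential decay: u = omega * tau
exp_phasor <- function(tau, omega) {
  u <- omega * tau
  c(G = 1 / (1 + u^2), S = u / (1 + u^2))
}

#' Bi-exponential decomposition of a phasor target
#'
#' Solves for the decay mixture that realises the model's phasor point at a
#' given pH. With the short component fixed at `tau_short`, the chord from
#' its universal-circle point through the target `(G, S)` meets the circle
#' again at the long component's point; the intensity fraction `f2` of the
#' long component is the interior division ratio. By phasor linearity the
#' photon-weighted mixture lands exactly on the target.
#'
#' @param model A [photophysics_model()].
#' @param ph pH at which to realise the decay.
#' @param omega Angular frequency in rad/ns.
#' @return List with `tau1` (short, ns), `tau2` (long, ns), `f2` (intensity
#'   fraction of the long component), and the `target` c(G, S).
#' @examples
#' decompose_biexponential(photophysics_model(), 7.4)
#' @export
decompose_biexponential <- function(model, ph, omega = 2 * pi * 0.08) {
  stopifnot(inherits(model, "photophysics_model"))
  target <- c(G = model_g(model, ph), S = model_s(model, ph, omega))
  r2 <- (target[1] - 0.5)^2 + target[2]^2
  if (r2 > 0.25 + 1e-12)
    abort(sprintf(
      "phasor target (G=%.4f, S=%.4f) at pH %.2f lies outside the universal semicircle: no non-negative decay mixture can realise it.",
      target[1], target[2], ph))
  if (abs(r2 - 0.25) < 1e-12) {
    # on the circle: degenerate single exponential
    tau <- unname(target[2] / (omega * target[1]))
    return(list(tau1 = tau, tau2 = tau, f2 = 1, target = unname(target)))
  }
  p1 <- exp_phasor(model$tau_short, omega)
  d <- target - p1
  # p1 lies on the circle, so s = 0 is one root; the chord's far intersection:
  a <- sum(d^2)
  b <- 2 * sum((p1 - c(0.5, 0)) * d)
  s2 <- -b / a
  if (s2 <= 1)
    abort(sprintf(
      "tau_short = %.3g ns is on the wrong side of the target at pH %.2f: choose a shorter component.",
      model$tau_short, ph))
  p2 <- p1 + s2 * d
  tau2 <- unname(p2[2] / (omega * p2[1]))
  list(tau1 = model$tau_short, tau2 = tau2, f2 = 1 / s2, target = unname(target))
}
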