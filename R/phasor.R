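#' Per-pixel phasor transform of a decay cube
#'
#' Maps every pixel's photon-arrival histogram to phasor coordinates
#' `(G, S)`: the cosine and sine first-harmonic Fourier coefficients of the
#' normalised decay,
#' \deqn{G = \frac{\sum_t c_t \cos(n\omega t)}{\sum_t c_t}, \qquad
#'       S = \frac{\sum_t c_t \sin(n\omega t)}{\sum_t c_t},}
#' with \eqn{\omega = 2\pi f_{rep}} the angular repetition frequency, `n` the
#' harmonic, and `t` the bin-centre arrival time. The transform is fit-free:
#' no decay model is assumed, and single-exponential decays fall on the
#' universal semicircle \eqn{(G - 1/2)^2 + S^2 = 1/4} while mixtures fall
#' inside it. Zero-photon pixels are masked invalid rather than NaN-filled so
#' photon-weighted summaries stay well defined.
#'
#' @param decay A [decay_image()].
#' @param harmonic Positive integer harmonic of the repetition frequency
#'   (default 1).
#' @param time_offset Constant instrument time offset in ns, subtracted from
#'   bin-centre times (default 0; an ideal delta excitation at t = 0 is
#'   assumed).
#' @return A `phasor_image`: list with `G`, `S` (matrices in `[-1, 1]`),
#'   `photons` (per-pixel totals), `omega` (rad/ns, includes the harmonic),
#'   `valid` (logical matrix), `pixel_size`.
#' @examples
#' d <- simulate_decay_pixels(photophysics_model(), ph = 7.4,
#'                            dim = c(8, 8), photons_per_pixel = 200, seed = 1)
#' p <- compute_phasor(d)
#' image_weighted_G(p)
#' @export
compute_phasor <- function(decay, harmonic = 1, time_offset = 0) {
  stopifnot(inherits(decay, "decay_image"))
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L) abort("`harmonic` must be a positive integer.")
  d <- dim(decay$counts)
  omega <- decay_omega(decay) * harmonic
  t_mid <- (seq_len(d[3]) - 0.5) * decay$bin_width - time_offset
  m <- matrix(decay$counts, d[1] * d[2], d[3])
  tot <- rowSums(m)
  G <- as.vector(m %*% cos(omega * t_mid))
  S <- as.vector(m %*% sin(omega * t_mid))
  valid <- tot > 0
  G <- ifelse(valid, G / tot, 0)
  S <- ifelse(valid, S / tot, 0)
  new_phasor_image(matrix(G, d[1], d[2]), matrix(S, d[1], d[2]),
                   matrix(tot, d[1], d[2]), omega,
                   matrix(valid, d[1], d[2]), decay$pixel_size)
}

new_phasor_image <- function(G, S, photons, omega, valid, pixel_size = 0.133) {
  stopifnot(is.matrix(G), all(dim(S) == dim(G)), all(dim(photons) == dim(G)),
            all(dim(valid) == dim(G)))
  structure(list(G = G, S = S, photons = photons, omega = omega,
                 valid = valid, pixel_size = pixel_size),
            class = "phasor_image")
}

#' Construct a phasor image from component grids
#'
#' Builds a `phasor_image` directly from per-pixel `(G, S, photons)` grids,
#' e.g. when re-importing instrument-exported phasor pages.
#'
#' @param G,S Real matrices of phasor coordinates.
#' @param photons Non-negative matrix of per-pixel photon totals.
#' @param omega Angular frequency in rad/ns.
#' @param valid Optional logical matrix; defaults to `photons > 0`.
#' @param pixel_size Pixel size in micrometres.
#' @return A `phasor_image`.
#' @export
phasor_image <- function(G, S, photons, omega, valid = NULL, pixel_size = 0.133) {
  if (is.null(valid)) valid <- photons > 0
  new_phasor_image(G, S, photons, omega, valid, pixel_size)
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf(
    "<phasor_image> %d x %d px, omega = %.5f rad/ns, %d/%d valid, %s photons\n",
    nrow(x$G), ncol(x$G), x$omega, sum(x$valid), length(x$valid),
    format(sum(x$photons), big.mark = ",")))
  invisible(x)
}

#' @export
dim.phasor_image <- function(x) dim(x$G)

#' Mask pixels below a photon-count threshold
#'
#' Applies the low-intensity cutoff used before all weighted summaries and
#' vesicle analysis: pixels with fewer than `min_photons` detected photons
#' are marked invalid (the default of 15 photons/pixel removes dim cytosolic
#' background while keeping vesicle signal). G and S values are untouched.
#'
#' @param phasor A `phasor_image`.
#' @param min_photons Non-negative integer threshold; pixels with
#'   `photons >= min_photons` stay valid.
#' @return The thresholded `phasor_image`.
#' @export
threshold_photons <- function(phasor, min_photons = 15) {
  stopifnot(inherits(phasor, "phasor_image"))
  if (min_photons < 0) abort("`min_photons` must be >= 0.")
  phasor$valid <- phasor$valid & (phasor$photons >= min_photons)
  phasor
}

#' Per-pixel fast (phase) lifetime
#'
#' Converts phasor coordinates to the fast lifetime reported by fast-FLIM
#' instruments, using the phase-lifetime estimator
#' \eqn{\tau_\phi = S / (\omega G)}. For a single-exponential decay
#' \eqn{\tau_\phi} equals the true lifetime; for mixtures it is a fit-free
#' apparent lifetime. Pixels with `G <= 0` or `S < 0` (unphysical for a
#' photon decay) are marked invalid.
#'
#' @param phasor A `phasor_image`.
#' @return A `fast_lifetime_image`: list with `tau` (ns matrix), `photons`,
#'   `valid`, `omega`, `pixel_size`.
#' @export
compute_fast_lifetime <- function(phasor) {
  stopifnot(inherits(phasor, "phasor_image"))
  valid <- phasor$valid & phasor$G > 0 & phasor$S >= 0
  tau <- matrix(0, nrow(phasor$G), ncol(phasor$G))
  tau[valid] <- phasor$S[valid] / (phasor$omega * phasor$G[valid])
  structure(list(tau = tau, photons = phasor$photons, valid = valid,
                 omega = phasor$omega, pixel_size = phasor$pixel_size),
            class = "fast_lifetime_image")
}

#' @export
print.fast_lifetime_image <- function(x, ...) {
  cat(sprintf("<fast_lifetime_image> %d x %d px, %d valid pixels\n",
              nrow(x$tau), ncol(x$tau), sum(x$valid)))
  invisible(x)
}

weighted_image_mean <- function(value, photons, valid, what) {
  if (!any(valid)) abort(sprintf("no valid pixels: cannot compute the %s.", what))
  w <- as.numeric(photons[valid])
  if (sum(w) <= 0) abort(sprintf("all valid pixels have zero photons: cannot compute the %s.", what))
  sum(w * value[valid]) / sum(w)
}

#' Photon-weighted image summaries
#'
#' `image_weighted_G()` computes the image-level mean weighted G value
#' \deqn{\bar G = \frac{\sum_{xy} P_{xy} G_{xy}}{\sum_{xy} P_{xy}}}
#' over valid pixels, weighting each pixel's phasor coordinate by its photon
#' count \eqn{P_{xy}}; `image_weighted_lifetime()` is the same summary for
#' the fast lifetime. Both are independent of overall brightness: scaling
#' every photon count leaves the result unchanged.
#'
#' @param phasor A `phasor_image`.
#' @param lifetimes A `fast_lifetime_image`.
#' @return A single numeric value (G, dimensionless; lifetime in ns).
#' @export
image_weighted_G <- function(phasor) {
  stopifnot(inherits(phasor, "phasor_image"))
  weighted_image_mean(phasor$G, phasor$photons, phasor$valid, "image-weighted G")
}

#' @rdname image_weighted_G
#' @export
image_weighted_lifetime <- function(lifetimes) {
  stopifnot(inherits(lifetimes, "fast_lifetime_image"))
  weighted_image_mean(lifetimes$tau, lifetimes$photons, lifetimes$valid,
                      "image-weighted lifetime")
}

#' Modal G value of an image
#'
#' Centre of the highest-mass bin of the photon-weighted G histogram, the
#' summary used to report the most common pH environment in an image. Ties
#' are broken toward lower G (higher pH).
#'
#' @param phasor A `phasor_image`.
#' @param bin_width G histogram bin width (default 0.01).
#' @return Numeric: the modal G (bin centre).
#' @export
modal_G <- function(phasor, bin_width = 0.01) {
  stopifnot(inherits(phasor, "phasor_image"))
  if (!any(phasor$valid)) abort("no valid pixels: cannot compute the modal G.")
  g <- phasor$G[phasor$valid]
  w <- as.numeric(phasor$photons[phasor$valid])
  idx <- floor(g / bin_width + 1e-9)
  mass <- tapply(w, idx, sum)
  centres <- (as.numeric(names(mass)) + 0.5) * bin_width
  best <- which(mass == max(mass))
  centres[best[which.min(centres[best])]]
}
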