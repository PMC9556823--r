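# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: plain loops and closed forms only.

# analytic per-bin photon masses of a single-exponential decay wrapped into
# one laser period (normalisation over the period included)
analytic_bin_masses <- function(tau, n_bins, period) {
  edges <- seq(0, period, length.out = n_bins + 1)
  m <- exp(-edges[-(n_bins + 1)] / tau) - exp(-edges[-1] / tau)
  m / (1 - exp(-period / tau))
}

# continuous-decay phasor closed form (wrap-invariant at harmonic 1)
closed_form_phasor <- function(tau, omega) {
  u <- omega * tau
  c(G = 1 / (1 + u^2), S = u / (1 + u^2))
}

# brute-force phasor of one pixel's histogram: explicit loop over bins
brute_phasor_pixel <- function(counts, bin_width, omega) {
  G <- 0; S <- 0; tot <- 0
  for (b in seq_along(counts)) {
    t_mid <- (b - 0.5) * bin_width
    G <- G + counts[b] * cos(omega * t_mid)
    S <- S + counts[b] * sin(omega * t_mid)
    tot <- tot + counts[b]
  }
  c(G = G / tot, S = S / tot)
}

# sort-based percentile with linear interpolation between order statistics
sort_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# hand-loop per-vesicle weighted G (Eq. 1 oracle)
brute_vesicle_G <- function(G, photons, valid, labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- data.frame(label = ids, weighted_g = NA_real_, total_photons = NA_real_)
  for (i in seq_along(ids)) {
    num <- 0; den <- 0
    for (px in which(labels == ids[i])) {
      if (valid[px]) { num <- num + photons[px] * G[px]; den <- den + photons[px] }
    }
    out$weighted_g[i] <- num / den
    out$total_photons[i] <- den
  }
  out
}

# uniform decay cube with analytically exact bin proportions at lifetime tau
analytic_decay <- function(tau, n_bins = 256, total_photons = 1e6,
                           dim = c(4, 4), rep_rate = 80) {
  period <- 1000 / rep_rate
  mass <- analytic_bin_masses(tau, n_bins, period)
  per_pixel <- round(total_photons / prod(dim) * mass)
  cube <- array(rep(per_pixel, each = prod(dim)), dim = c(dim, n_bins))
  decay_image(cube, period / n_bins, rep_rate)
}

ref_pairs <- data.frame(g = c(0.39, 0.45, 0.52, 0.57, 0.62),
                        ph = c(7.4, 6.8, 6.1, 5.6, 5.1))
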