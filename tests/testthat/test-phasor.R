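test_that("phasor limits: zero-lifetime and the omega*tau = 1 point", {
  # all photons in the first of many bins: t_mid -> 0, so G -> 1, S -> 0
  n_bins <- 2048
  cube <- array(0L, dim = c(2, 2, n_bins)); cube[, , 1] <- 1000L
  p <- compute_phasor(decay_image(cube, 12.5 / n_bins))
  expect_equal(p$G[1, 1], 1, tolerance = 1e-5)
  expect_equal(p$S[1, 1], 0, tolerance = 1e-2)
  # single exponential with omega * tau = 1 sits at (0.5, 0.5)
  omega <- 2 * pi * 0.08
  d <- analytic_decay(1 / omega, n_bins = 512)
  p2 <- compute_phasor(d)
  expect_equal(p2$G[1, 1], 0.5, tolerance = 1e-4)
  expect_equal(p2$S[1, 1], 0.5, tolerance = 1e-4)
})

test_that("single-exponential phasor matches the closed form (tau = 2.2 ns, 80 MHz)", {
  omega <- 2 * pi * 0.08
  cf <- closed_form_phasor(2.2, omega)
  expect_equal(unname(cf["G"]), 0.4499, tolerance = 1e-3)
  expect_equal(unname(cf["S"]), 0.4975, tolerance = 1e-3)
  p <- compute_phasor(analytic_decay(2.2, n_bins = 512))
  expect_equal(p$G[1, 1], unname(cf["G"]), tolerance = 5e-4)
  expect_equal(p$S[1, 1], unname(cf["S"]), tolerance = 5e-4)
})

test_that("compute_phasor agrees with a per-pixel brute-force loop", {
  set.seed(7)
  cube <- array(rpois(3 * 4 * 24, 15), dim = c(3, 4, 24))
  d <- decay_image(cube, 0.4)
  p <- compute_phasor(d)
  for (i in 1:3) for (j in 1:4) {
    ref <- brute_phasor_pixel(cube[i, j, ], 0.4, decay_omega(d))
    expect_equal(p$G[i, j], unname(ref["G"]), tolerance = 1e-12)
    expect_equal(p$S[i, j], unname(ref["S"]), tolerance = 1e-12)
  }
  expect_equal(p$photons, apply(cube, c(1, 2), sum), ignore_attr = TRUE)
})

test_that("phasor is exactly invariant to photon-count scaling and masks empty pixels", {
  set.seed(8)
  cube <- array(rpois(4 * 4 * 16, 10), dim = c(4, 4, 16))
  cube[2, 3, ] <- 0L
  d1 <- decay_image(cube, 12.5 / 16)
  d3 <- decay_image(cube * 3L, 12.5 / 16)
  p1 <- compute_phasor(d1); p3 <- compute_phasor(d3)
  expect_equal(p1$G[p1$valid], p3$G[p3$valid], tolerance = 1e-14)
  expect_false(p1$valid[2, 3])
  expect_false(anyNA(p1$G))
})

test_that("universal-circle identities hold for simulated decays", {
  omega <- 2 * pi * 0.08
  for (tau in c(0.8, 1.5, 2.2, 3.5)) {
    d <- analytic_decay(tau, n_bins = 256, total_photons = 4e4)
    p <- compute_phasor(d)
    g <- p$G[1, 1]; s <- p$S[1, 1]
    expect_lt(abs(s^2 + g^2 - g), 0.01)
  }
  # mixtures fall inside the semicircle
  m <- photophysics_model()
  for (ph in seq(4.6, 7.4, length.out = 7)) {
    d <- simulate_decay_pixels(m, ph, dim = c(4, 4), photons_per_pixel = 3000,
                               seed = round(ph * 100))
    p <- compute_phasor(d)
    g <- mean(p$G); s <- mean(p$S)
    expect_lt((g - 0.5)^2 + s^2, 0.25 + 0.01)
  }
})

test_that("threshold_photons is boundary-inclusive and monotone", {
  ph <- phasor_image(G = matrix(0.5, 1, 3), S = matrix(0.4, 1, 3),
                     photons = matrix(c(10, 15, 20), 1), omega = 0.5)
  expect_equal(as.vector(threshold_photons(ph, 15)$valid), c(FALSE, TRUE, TRUE))
  expect_equal(threshold_photons(ph, 0)$valid, ph$valid)
  n_valid <- vapply(c(0, 5, 10, 15, 20, 25),
                    function(k) sum(threshold_photons(ph, k)$valid), 0)
  expect_true(all(diff(n_valid) <= 0))
})

test_that("image-weighted summaries follow the weighted-mean definitions", {
  ph <- phasor_image(G = matrix(c(0.5, 0.7), 1), S = matrix(0.4, 1, 2),
                     photons = matrix(c(10, 30), 1), omega = 0.5)
  expect_equal(image_weighted_G(ph), 0.65)
  # uniform G is returned untouched whatever the photon pattern
  phu <- phasor_image(G = matrix(0.42, 2, 2), S = matrix(0.4, 2, 2),
                      photons = matrix(c(1, 50, 7, 300), 2), omega = 0.5)
  expect_equal(image_weighted_G(phu), 0.42)
  # concentration independence
  ph_k <- ph; ph_k$photons <- ph$photons * 17
  expect_equal(image_weighted_G(ph_k), image_weighted_G(ph))
  # permutation invariance and boundedness
  set.seed(3)
  G <- matrix(runif(25, 0.3, 0.7), 5); P <- matrix(rpois(25, 40) + 1, 5)
  pha <- phasor_image(G, G * 0.8, P, 0.5)
  perm <- sample(25)
  phb <- phasor_image(matrix(G[perm], 5), matrix(G[perm] * 0.8, 5),
                      matrix(P[perm], 5), 0.5)
  expect_equal(image_weighted_G(pha), image_weighted_G(phb))
  expect_gte(image_weighted_G(pha), min(G))
  expect_lte(image_weighted_G(pha), max(G))
  expect_error(image_weighted_G(phasor_image(G, G, P * 0, 0.5)), "no valid pixels")
})

test_that("image_weighted_lifetime matches hand arithmetic", {
  mk <- function(tau, photons) {
    structure(list(tau = matrix(tau, 1), photons = matrix(photons, 1),
                   valid = matrix(TRUE, 1, length(tau)), omega = 0.5,
                   pixel_size = 0.133), class = "fast_lifetime_image")
  }
  expect_equal(image_weighted_lifetime(mk(c(1, 3), c(1, 1))), 2)
  expect_equal(image_weighted_lifetime(mk(c(2, 1), c(10, 30))), 1.25)
  expect_equal(image_weighted_lifetime(mk(2.7, 5)), 2.7)
})

test_that("phase lifetime is S/(omega G) with validity propagation", {
  omega <- 2 * pi * 0.08
  ph <- phasor_image(G = matrix(c(0.5, 0.39, 0.5, -0.1), 1),
                     S = matrix(c(0.5, omega * 2.2 * 0.39, 0, 0.2), 1),
                     photons = matrix(10, 1, 4), omega = omega)
  lt <- compute_fast_lifetime(ph)
  expect_equal(lt$tau[1, 1], 1 / omega, tolerance = 1e-12)
  expect_equal(lt$tau[1, 2], 2.2, tolerance = 1e-12)
  expect_equal(lt$tau[1, 3], 0)
  expect_false(lt$valid[1, 4])  # G <= 0 is unphysical
})

test_that("modal_G picks the heaviest histogram bin with ties toward lower G", {
  phu <- phasor_image(G = matrix(0.45, 2, 2), S = matrix(0.4, 2, 2),
                      photons = matrix(5, 2, 2), omega = 0.5)
  expect_lt(abs(modal_G(phu) - 0.45), 0.005 + 1e-12)
  pht <- phasor_image(G = matrix(c(0.40, 0.60), 1), S = matrix(0.4, 1, 2),
                      photons = matrix(c(10, 10), 1), omega = 0.5)
  expect_lt(abs(modal_G(pht) - 0.40), 0.005 + 1e-12)
})

test_that("modal G of a two-population image tracks the dominant population", {
  m <- photophysics_model()
  # 70% of photons at pH 5.1 (G ~ 0.62), 30% at pH 6.8 (G ~ 0.45)
  d_lo <- simulate_decay_pixels(m, 5.1, dim = c(14, 20), photons_per_pixel = 3000,
                                seed = 21)
  d_hi <- simulate_decay_pixels(m, 6.8, dim = c(6, 20), photons_per_pixel = 3000,
                                seed = 22)
  cube <- array(0L, dim = c(20, 20, 128))
  cube[1:14, , ] <- d_lo$counts
  cube[15:20, , ] <- d_hi$counts
  p <- compute_phasor(decay_image(cube, d_lo$bin_width))
  expect_lt(abs(modal_G(p) - 0.62), 0.01)
})
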