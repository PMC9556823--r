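make_phasor <- function(G, photons, omega = 2 * pi * 0.08, valid = NULL) {
  phasor_image(G, G * 0, photons, omega, valid)
}

test_that("per-vesicle weighted G follows the weighted-mean definition", {
  G <- matrix(c(0.5, 0.7, 0.9, 0.1), 2)
  P <- matrix(c(10, 30, 5, 5), 2)
  lab <- matrix(c(1L, 1L, 0L, 0L), 2)
  res <- vesicle_weighted_G(make_phasor(G, P), label_mask(lab, 0.133))
  expect_equal(res$weighted_g, 0.65)
  expect_equal(res$total_photons, 40)
  # uniform-G region returns that G whatever the photon pattern
  Gu <- matrix(0.42, 3, 3); Pu <- matrix(c(1, 2, 500, 1, 9, 3, 80, 2, 7), 3)
  labu <- matrix(1L, 3, 3)
  expect_equal(vesicle_weighted_G(make_phasor(Gu, Pu),
                                  label_mask(labu, 0.133))$weighted_g, 0.42)
})

test_that("vesicle weighted G equals a brute-force per-pixel loop on random masks", {
  set.seed(20)
  for (i in 1:40) {
    G <- matrix(runif(64, 0.3, 0.7), 8)
    P <- matrix(rpois(64, 25), 8)
    valid <- matrix(runif(64) > 0.1, 8)
    lab <- matrix(sample(0:3, 64, replace = TRUE), 8)
    res <- vesicle_weighted_G(
      suppressWarnings(make_phasor(G, P, valid = valid)),
      label_mask(lab, 0.133, compact = FALSE))
    ref <- brute_vesicle_G(G, P, valid, lab)
    ref <- ref[match(res$label, ref$label), ]
    expect_equal(res$weighted_g, ref$weighted_g, tolerance = 1e-12)
    expect_equal(res$total_photons, ref$total_photons, tolerance = 1e-12)
  }
})

test_that("splitting a vesicle and photon-weight-averaging the halves is exact", {
  set.seed(21)
  G <- matrix(runif(36, 0.4, 0.6), 6); P <- matrix(rpois(36, 40) + 1, 6)
  whole <- matrix(0L, 6, 6); whole[2:5, 2:5] <- 1L
  halves <- whole; halves[2:5, 4:5] <- 2L
  ph <- make_phasor(G, P)
  w <- vesicle_weighted_G(ph, label_mask(whole, 0.133))
  h <- vesicle_weighted_G(ph, label_mask(halves, 0.133))
  recomb <- sum(h$weighted_g * h$total_photons) / sum(h$total_photons)
  expect_equal(recomb, w$weighted_g, tolerance = 1e-14)
})

test_that("vesicle_table converts G to pH consistently and measures intra-vesicle spread", {
  cal <- default_g_calibration()
  G <- matrix(0.52, 5, 5); P <- matrix(20, 5, 5)
  lab <- matrix(0L, 5, 5); lab[2:4, 2:4] <- 1L
  vt <- vesicle_table(make_phasor(G, P), label_mask(lab, 0.133), cal)
  expect_equal(nrow(vt), 1)
  expect_equal(vt$ph, g_to_ph(vt$weighted_g, cal)$ph, tolerance = 1e-9)
  expect_equal(vt$ph, 6.1, tolerance = 1e-9)
  expect_equal(vt$ph_sd, 0)              # noiseless uniform region
  expect_equal(vt$area_px, 9L)
  expect_equal(vt$centroid_row, 2)       # 0-based centre of rows 2:4 (1-based)
  # mixed-G region: pH consistent with Eq. 1, spread positive
  G2 <- G; G2[2, 2] <- 0.60
  vt2 <- vesicle_table(make_phasor(G2, P), label_mask(lab, 0.133), cal)
  expect_equal(vt2$ph, g_to_ph(vt2$weighted_g, cal)$ph, tolerance = 1e-9)
  expect_gt(vt2$ph_sd, 0)
})

test_that("programmed vesicle pH is recovered from simulated scenes", {
  sc <- simulate_cell_scene(
    scene_spec(dim = c(150, 150), n_vesicles = 15, ph = c(5, 6, 7),
               photons_per_vesicle = 3e4, seed = 41),
    photophysics_model())
  a <- analyze_scene(sc, use_truth_mask = TRUE)
  err <- a$vesicles$ph - sc$truth$ph[a$vesicles$label]
  expect_lt(sqrt(mean(err^2)), 0.1)
  expect_lt(abs(mean(err)), 0.05)
})

test_that("image summaries: mean, degenerate majority interval, quantile oracle", {
  rec <- tibble::tibble(ph = c(5, 6, 7), total_photons = c(1, 1, 1))
  s <- summarize_image(rec)
  expect_equal(s$mean_ph, 6)
  expect_equal(s$n_vesicles, 3)
  same <- tibble::tibble(ph = rep(5.5, 8), total_photons = 1)
  s2 <- summarize_image(same)
  expect_equal(c(s2$majority_low, s2$majority_high), c(5.5, 5.5))
  set.seed(30)
  for (i in 1:30) {
    ph <- runif(sample(5:60, 1), 4.5, 7.5)
    s3 <- summarize_image(tibble::tibble(ph = ph, total_photons = 1))
    expect_equal(s3$majority_low, sort_percentile(ph, 12.5), tolerance = 1e-12)
    expect_equal(s3$majority_high, sort_percentile(ph, 87.5), tolerance = 1e-12)
  }
  expect_error(summarize_image(tibble::tibble(ph = double())), "empty")
})

test_that("time-course comparison is the classic equal-variance t-test", {
  a <- data.frame(timepoint = 0, mean_ph = c(5.5, 5.6, 5.4))
  # identical groups: t = 0, p = 1
  res <- timecourse_compare(a, a)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # textbook fixture, hand-computed pooled-variance t
  xa <- c(5.1, 5.3, 5.2); xb <- c(5.6, 5.8, 5.7)
  sp2 <- (2 * var(xa) + 2 * var(xb)) / 4
  t_ref <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  res2 <- timecourse_compare(data.frame(timepoint = 1, mean_ph = xa),
                             data.frame(timepoint = 1, mean_ph = xb))
  expect_equal(res2$t_stat, t_ref, tolerance = 1e-12)
  expect_equal(res2$p_value, 2 * pt(t_ref, df = 4), tolerance = 1e-12)
  expect_lt(res2$p_value, 0.05)  # ~10 sigma effect with n = 3
  expect_error(timecourse_compare(a, data.frame(timepoint = 0, mean_ph = 5)),
               "fewer than 2 replicates")
})

test_that("cargo-pH correlation handles perfect, null and degenerate inputs", {
  rec <- tibble::tibble(ph = seq(5, 6, length.out = 10),
                        aux_cy5 = seq(100, 1000, length.out = 10))
  cc <- cargo_ph_correlation(rec, "cy5")
  expect_equal(cc$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cc$spearman_rho, 1, tolerance = 1e-12)
  set.seed(50)
  null_rec <- tibble::tibble(ph = rnorm(1000, 5.5, 0.3),
                             aux_cy5 = rlnorm(1000, log(800), 0.5))
  cc0 <- cargo_ph_correlation(null_rec, "cy5")
  expect_lt(abs(cc0$pearson_r), 0.1)
  expect_lt(abs(cc0$spearman_rho), 0.1)
  expect_warning(ccc <- cargo_ph_correlation(
    tibble::tibble(ph = c(5, 6, 7), aux_cy5 = c(4, 4, 4)), "cy5"), "constant")
  expect_true(is.na(ccc$pearson_r))
  expect_error(cargo_ph_correlation(rec[1:2, ], "cy5"), "at least 3")
})
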