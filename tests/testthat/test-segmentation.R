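test_that("percentile normalisation rescales, clips, and matches a sort-based oracle", {
  img <- matrix(0:99, 10)
  expect_equal(normalize_percentiles(img, 0, 100), img / 99)
  set.seed(12)
  for (i in 1:25) {
    x <- matrix(runif(400, 0, 100), 20)
    n <- normalize_percentiles(x, 25, 99.8)
    expect_equal(min(n), 0); expect_equal(max(n), 1)
    q_lo <- sort_percentile(as.vector(x), 25)
    q_hi <- sort_percentile(as.vector(x), 99.8)
    mid <- x[x > q_lo & x < q_hi]
    expect_equal(n[x > q_lo & x < q_hi], (mid - q_lo) / (q_hi - q_lo),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(normalize_percentiles(matrix(5, 4, 4), 25, 99.8), "constant")
  expect_error(normalize_percentiles(img, 60, 40), "smaller")
})

test_that("blank or constant images yield an empty mask with a warning", {
  expect_warning(m <- detect_vesicles(matrix(0, 32, 32), segmentation_params()),
                 "constant|empty")
  expect_equal(n_labels(m), 0)
})

test_that("well-separated simulated vesicles are recalled at IoU >= 0.5", {
  sc <- simulate_cell_scene(
    scene_spec(dim = c(220, 220), n_vesicles = 50, photons_per_vesicle = 1e4,
               seed = 31),
    photophysics_model())
  p <- threshold_photons(compute_phasor(sc$decay), 15)
  # standard workflow: detect, then trim regions with the photon threshold
  mask <- filter_labels(detect_vesicles(p$photons, segmentation_params()),
                        p$photons)
  tm <- sc$truth_mask$labels; dm <- mask$labels
  iou <- vapply(seq_len(max(tm)), function(k) {
    pix <- tm == k
    cand <- dm[pix]; cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    lab <- as.integer(names(which.max(table(cand))))
    sum(pix & dm == lab) / sum(pix | dm == lab)
  }, 0)
  expect_gte(mean(iou >= 0.5), 0.9)
  # false positives: detections overlapping no true vesicle
  fp <- vapply(seq_len(n_labels(mask)),
               function(k) all(tm[dm == k] == 0), TRUE)
  expect_lte(mean(fp), 0.10)
  # determinism
  mask2 <- filter_labels(detect_vesicles(p$photons, segmentation_params()),
                         p$photons)
  expect_identical(mask$labels, mask2$labels)
})

test_that("two vesicles separated by background are never merged", {
  img <- matrix(0, 40, 40)
  bump <- function(r0, c0, amp = 200, sig = 2.5) {
    for (r in 1:40) for (c in 1:40)
      img[r, c] <<- img[r, c] + amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sig^2))
  }
  bump(15, 15); bump(15, 26)  # ~11 px apart, > 2 px of background between
  set.seed(99); img <- img + matrix(runif(1600, 0, 2), 40)
  mask <- detect_vesicles(img, segmentation_params())
  expect_equal(n_labels(mask), 2)
  lab_a <- mask$labels[15, 15]; lab_b <- mask$labels[15, 26]
  expect_true(lab_a > 0 && lab_b > 0 && lab_a != lab_b)
})

test_that("the external-model backend adopts a supplied label image", {
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 7L; lab[7:9, 7:9] <- 2L
  m <- detect_vesicles(matrix(1, 10, 10),
                       segmentation_params(backend = "external-model",
                                           external_labels = lab))
  expect_equal(n_labels(m), 2)
  expect_equal(sort(unique(as.vector(m$labels))), c(0L, 1L, 2L))
})

test_that("area cutoff at 2 um^2 removes regions above ~113 px at 133 nm pixels", {
  cutoff_px <- floor(2 / 0.133^2)  # 113
  lab <- matrix(0L, 40, 40)
  lab[1:10, 1:12] <- 1L             # 120 px: above cutoff, removed
  lab[20:30, 20:29] <- 2L           # 110 px: kept
  mask <- label_mask(lab, 0.133)
  photons <- matrix(100, 40, 40)
  f <- filter_labels(mask, photons)
  expect_equal(n_labels(f), 1)
  expect_true(all(f$labels[20:30, 20:29] == 1L))
  # boundary: exactly at the cutoff stays, one pixel more goes
  lab113 <- matrix(0L, 40, 40); lab113[seq_len(cutoff_px)] <- 1L
  expect_equal(n_labels(filter_labels(label_mask(lab113, 0.133), photons)), 1)
  lab114 <- matrix(0L, 40, 40); lab114[seq_len(cutoff_px + 1)] <- 1L
  expect_equal(n_labels(filter_labels(label_mask(lab114, 0.133), photons)), 0)
})

test_that("filter_labels with infinite area and zero photon threshold is the identity, and is monotone", {
  set.seed(5)
  lab <- EBImage::bwlabel(matrix(rbinom(900, 1, 0.2), 30))
  mask <- label_mask(as.matrix(lab), 0.133)
  photons <- matrix(rpois(900, 30), 30)
  id <- filter_labels(mask, photons, max_area_um2 = Inf, min_photons = 0)
  expect_equal(id$labels, mask$labels)
  areas <- c(Inf, 0.5, 0.2, 0.1, 0.05)
  counts <- vapply(areas, function(a)
    n_labels(filter_labels(mask, photons, max_area_um2 = a)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("label-wise erosion shrinks regions without merging and drops extinct ones", {
  lab <- matrix(0L, 12, 12)
  lab[3:7, 3:7] <- 1L      # 5x5 -> erodes to 3x3
  lab[10, 10] <- 2L        # single pixel -> extinct
  mask <- label_mask(lab, 0.133)
  e <- erode_labels(mask, 1)
  expect_equal(n_labels(e), 1)
  expect_equal(sum(e$labels > 0), 9)
  expect_true(all(e$labels[4:6, 4:6] == 1L))
  expect_equal(erode_labels(mask, 0)$labels, mask$labels)
  # adversarial: two touching labels must never merge under erosion
  lab2 <- matrix(0L, 10, 14)
  lab2[2:9, 2:7] <- 1L; lab2[2:9, 8:13] <- 2L  # share a vertical boundary
  e2 <- erode_labels(label_mask(lab2, 0.133), 1)
  expect_equal(n_labels(e2), 2)
  expect_equal(length(intersect(which(e2$labels == 1L), which(e2$labels == 2L))), 0)
  # erosion ate the shared boundary on both sides
  expect_true(all(e2$labels[, 7] == 0) && all(e2$labels[, 8] == 0))
})

test_that("double-positive classification uses original extents against eroded partners", {
  base <- matrix(0L, 20, 20)
  a <- base; a[3:6, 3:6] <- 1L; a[12:15, 12:15] <- 2L
  mask_a <- label_mask(a, 0.133)
  # disjoint partner: nothing double positive
  b_far <- base; b_far[17:19, 2:4] <- 1L
  res <- double_positive_mask(mask_a, label_mask(b_far, 0.133))
  expect_equal(n_labels(res$dp), 0)
  expect_equal(res$a_only$labels, mask_a$labels)
  # identical partner: everything double positive
  res2 <- double_positive_mask(mask_a, mask_a)
  expect_equal(res2$dp$labels, mask_a$labels)
  expect_equal(n_labels(res2$a_only), 0)
  # partner touching only at a boundary pixel that erosion removes
  b_touch <- base; b_touch[6:9, 6:9] <- 1L   # overlaps A region 1 only at (6,6)
  eroded <- erode_labels(label_mask(b_touch, 0.133), 1)
  res3 <- double_positive_mask(mask_a, eroded)
  expect_equal(n_labels(res3$dp), 0)         # classified A-only
  expect_equal(n_labels(res3$a_only), 2)
  expect_error(double_positive_mask(mask_a, label_mask(matrix(0L, 5, 5), 0.133)),
               "shape")
})

test_that("coincidence percentage is the double-positive fraction of A vesicles", {
  mk <- function(n) {
    lab <- matrix(0L, 10, 10)
    for (k in seq_len(n)) lab[k * 2, 2] <- k
    label_mask(lab, 0.133)
  }
  expect_equal(coincidence_percent(mk(3), mk(4)), 75)
  expect_equal(coincidence_percent(mk(0), mk(4)), 0)
  expect_equal(coincidence_percent(mk(4), mk(4)), 100)
  expect_warning(z <- coincidence_percent(mk(2), mk(0)), "no vesicles")
  expect_equal(z, 0)
})
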