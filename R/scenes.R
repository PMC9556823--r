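#' Specification of a synthetic vesicle scene
#'
#' Describes a cell-like field of endo/lysosomal vesicles for the FLIM
#' simulator: geometry, per-vesicle pH distribution, photon budgets and an
#' optional co-imaged cargo channel. All randomness flows from `seed`, so a
#' scene spec is a complete, bit-reproducible description.
#'
#' @param dim Image size `c(height, width)` in pixels (default 256 x 256 at
#'   133 nm/px, a ~34 um field).
#' @param n_vesicles Number of vesicles (default 100).
#' @param radius_range Vesicle radii are drawn uniformly from this range in
#'   pixels (default 2.5-5 px at 133 nm/px, i.e. 0.67-1.33 um diameter —
#'   the size scale of late endosomes and lysosomes).
#' @param ph Per-vesicle pH: a function `function(n)` returning `n` draws, or
#'   a numeric vector recycled to `n_vesicles`. Default: uniform over the
#'   physiological 4.6-7.4 range.
#' @param photons_per_vesicle Nominal photon budget of a vesicle at the
#'   reference pH (7.4); the realised budget is scaled by the model's
#'   relative intensity at the vesicle's pH, so acidic vesicles are dimmer
#'   (default 3e4, a few hundred photons at the brightest pixels, matching
#'   high-flux fast-FLIM acquisition with line accumulation).
#' @param background_rate Mean background photons per pixel (default 1).
#' @param background_ph pH of the diffuse background signal (default 7.4,
#'   cytosolic).
#' @param min_separation Minimum centre-to-centre distance in px (default
#'   `2 * max(radius_range) + 3`, which keeps vesicle discs disjoint with
#'   at least ~3 px of background between them).
#' @param n_bins Decay histogram bins (default 64).
#' @param aux_fraction Fraction of vesicles positive in the auxiliary cargo
#'   channel (e.g. Cy5-labelled polymer; default 0 = no aux channel).
#' @param aux_intensity Sampler `function(n)` for total cargo intensity per
#'   positive vesicle (default log-normal around 1000 counts).
#' @param aux_coupling Coupling of vesicle pH to cargo load, in pH units per
#'   SD of log cargo intensity (default 0: the null scenario in which cargo
#'   load and pH are independent).
#' @param seed Integer seed (mandatory).
#' @return A `scene_spec` list.
#' @seealso [simulate_cell_scene()], [simulate_timecourse()]
#' @export
scene_spec <- function(dim = c(256, 256), n_vesicles = 100,
                       radius_range = c(2.5, 5),
                       ph = function(n) runif(n, 4.6, 7.4),
                       photons_per_vesicle = 3e4,
                       background_rate = 1, background_ph = 7.4,
                       min_separation = NULL, n_bins = 64,
                       aux_fraction = 0,
                       aux_intensity = function(n) stats::rlnorm(n, log(1000), 0.5),
                       aux_coupling = 0, seed) {
  if (missing(seed) || !is.numeric(seed))
    abort("`seed` is mandatory: scenes must be bit-reproducible.")
  if (is.null(min_separation)) min_separation <- 2 * max(radius_range) + 3
  if (!is.function(ph)) {
    ph_vals <- rep_len(as.numeric(ph), n_vesicles)
    ph <- function(n) ph_vals[seq_len(n)]
  }
  structure(list(dim = dim, n_vesicles = n_vesicles, radius_range = radius_range,
                 ph = ph, photons_per_vesicle = photons_per_vesicle,
                 background_rate = background_rate, background_ph = background_ph,
                 min_separation = min_separation, n_bins = n_bins,
                 aux_fraction = aux_fraction, aux_intensity = aux_intensity,
                 aux_coupling = aux_coupling, seed = as.integer(seed)),
            class = "scene_spec")
}

place_vesicles <- function(spec) {
  h <- spec$dim[1]; w <- spec$dim[2]
  rmax <- max(spec$radius_range)
  if (h < 2 * rmax + 2 || w < 2 * rmax + 2)
    abort("scene too small for the requested vesicle radii.")
  rows <- numeric(0); cols <- numeric(0)
  radii <- runif(spec$n_vesicles, spec$radius_range[1], spec$radius_range[2])
  tries <- 0L; max_tries <- 2000L * spec$n_vesicles
  while (length(rows) < spec$n_vesicles) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort(sprintf(
        "could not place %d vesicles at min separation %.1f px in a %d x %d scene (overcrowded spec).",
        spec$n_vesicles, spec$min_separation, h, w))
    r <- radii[length(rows) + 1]
    cand_r <- runif(1, r + 1, h - r)
    cand_c <- runif(1, r + 1, w - r)
    if (length(rows) == 0 ||
        all((rows - cand_r)^2 + (cols - cand_c)^2 >= spec$min_separation^2)) {
      rows <- c(rows, cand_r); cols <- c(cols, cand_c)
    }
  }
  tibble(label = seq_len(spec$n_vesicles), row = rows, col = cols,
         radius_px = radii)
}

# disc pixels and normalised Gaussian weights for one vesicle
vesicle_footprint <- function(row0, col0, r, h, w) {
  rr <- max(1, floor(row0 - r)):min(h, ceiling(row0 + r))
  cc <- max(1, floor(col0 - r)):min(w, ceiling(col0 + r))
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - row0)^2 + (g$col - col0)^2
  inside <- d2 <= r^2
  g <- g[inside, , drop = FALSE]
  sigma <- r / 2
  wgt <- exp(-d2[inside] / (2 * sigma^2))
  list(row = g$row, col = g$col, weight = wgt / sum(wgt))
}

#' Simulate a vesicle scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: vesicles as
#' Gaussian-profile discs whose photon budgets scale with the model's
#' pH-dependent emission intensity, a dim diffuse background at cytosolic
#' pH, per-photon arrival times drawn from each vesicle's bi-exponential
#' decay, and (optionally) a coincident cargo-intensity channel. The ground
#' truth — label mask and per-vesicle table — is returned alongside, so the
#' whole detection/quantification pipeline can be scored against it.
#'
#' @param spec A [scene_spec()].
#' @param model A [photophysics_model()].
#' @param placement Optional pre-computed placement (internal; used by
#'   [simulate_timecourse()] to hold geometry fixed).
#' @param ph_override Optional numeric vector of per-vesicle pH values
#'   overriding the spec's sampler.
#' @return A `flim_scene`: list with `decay` ([decay_image()]), `aux`
#'   (named list of intensity matrices, possibly empty), `truth_mask`
#'   ([label_mask()]), `truth` (tibble: `label`, `row`, `col` 0-based,
#'   `radius_px`, `ph`, `budget`, `aux_positive`, `aux_intensity`), plus the
#'   `spec` and `model` used.
#' @examples
#' sc <- simulate_cell_scene(scene_spec(dim = c(64, 64), n_vesicles = 4,
#'                                      photons_per_vesicle = 2000, seed = 3))
#' sc$truth
#' @export
simulate_cell_scene <- function(spec, model = photophysics_model(),
                                placement = NULL, ph_override = NULL) {
  stopifnot(inherits(spec, "scene_spec"), inherits(model, "photophysics_model"))
  set.seed(spec$seed)
  if (is.null(placement)) placement <- place_vesicles(spec)
  n <- nrow(placement)
  ph <- if (is.null(ph_override)) spec$ph(n) else rep_len(ph_override, n)

  aux_positive <- rep(FALSE, n)
  aux_int <- rep(0, n)
  if (spec$aux_fraction > 0) {
    aux_positive <- seq_len(n) %in%
      sample.int(n, size = round(spec$aux_fraction * n))
    aux_int[aux_positive] <- spec$aux_intensity(sum(aux_positive))
    if (spec$aux_coupling != 0) {
      z <- scale(log(aux_int[aux_positive]))[, 1]
      if (anyNA(z)) z <- rep(0, sum(aux_positive))
      ph[aux_positive] <- ph[aux_positive] + spec$aux_coupling * z
    }
  }

  h <- spec$dim[1]; w <- spec$dim[2]; npix <- h * w
  rep_rate <- 80
  period <- 1000 / rep_rate
  omega <- 2 * pi * rep_rate / 1000
  n_bins <- spec$n_bins
  bin_width <- period / n_bins

  labels <- matrix(0L, h, w)
  aux_img <- if (any(aux_positive)) matrix(0, h, w) else NULL
  pix_all <- integer(0); bin_all <- integer(0)
  budget <- numeric(n)

  for (i in seq_len(n)) {
    fp <- vesicle_footprint(placement$row[i], placement$col[i],
                            placement$radius_px[i], h, w)
    idx <- fp$row + (fp$col - 1L) * h
    labels[idx] <- i
    budget[i] <- spec$photons_per_vesicle * model_intensity(model, ph[i])
    counts <- rpois(length(idx), budget[i] * fp$weight)
    tot <- sum(counts)
    if (tot > 0) {
      decomp <- decompose_biexponential(model, ph[i], omega)
      t <- sample_biexp_times(tot, decomp, period)
      pix_all <- c(pix_all, rep.int(idx, counts))
      bin_all <- c(bin_all, pmin(floor(t / bin_width) + 1L, n_bins))
    }
    if (aux_positive[i]) aux_img[idx] <- aux_img[idx] + rpois(length(idx), aux_int[i] * fp$weight)
  }

  if (spec$background_rate > 0) {
    bg_counts <- rpois(npix, spec$background_rate)
    totbg <- sum(bg_counts)
    if (totbg > 0) {
      decomp <- decompose_biexponential(model, spec$background_ph, omega)
      t <- sample_biexp_times(totbg, decomp, period)
      pix_all <- c(pix_all, rep.int(seq_len(npix), bg_counts))
      bin_all <- c(bin_all, pmin(floor(t / bin_width) + 1L, n_bins))
    }
  }

  cube <- array(tabulate(pix_all + (bin_all - 1L) * npix, nbins = npix * n_bins),
                dim = c(h, w, n_bins))
  decay <- decay_image(cube, bin_width, rep_rate)
  truth <- placement |>
    dplyr::mutate(row = .data$row - 1, col = .data$col - 1,  # 0-based coords
                  ph = ph, budget = budget,
                  aux_positive = aux_positive, aux_intensity = aux_int)
  aux <- if (is.null(aux_img)) list() else list(cy5 = aux_img)
  structure(list(decay = decay, aux = aux,
                 truth_mask = label_mask(labels, pixel_size = 0.133),
                 truth = truth, spec = spec, model = model),
            class = "flim_scene")
}

#' @export
print.flim_scene <- function(x, ...) {
  cat(sprintf("<flim_scene> %d x %d px, %d vesicle(s), %s photons, %d aux channel(s)\n",
              dim(x$decay)[1], dim(x$decay)[2], nrow(x$truth),
              format(sum(x$decay$counts), big.mark = ","), length(x$aux)))
  invisible(x)
}

#' Simulate a treatment time course over a fixed vesicle field
#'
#' Re-renders the same vesicle geometry at successive timepoints with
#' per-vesicle pH drawn around a drifting mean — the design of a V-ATPase
#' inhibition experiment (mean rising 5.3 to 6.5 over an hour) or of an
#' untreated/null arm (flat mean). Per-timepoint seeds are derived from the
#' spec seed, so the series is reproducible while timepoints stay
#' independent draws.
#'
#' @param spec A [scene_spec()]; its `ph` sampler is ignored in favour of
#'   the drift.
#' @param model A [photophysics_model()].
#' @param drift Data frame with columns `time_min` and `mean_ph`.
#' @param ph_sd SD of per-vesicle pH around the drifting mean (default
#'   0.15, the scale of vesicle-to-vesicle heterogeneity within one
#'   compartment class).
#' @return Tibble with columns `time_min`, `mean_ph` (programmed), and a
#'   `scene` list-column of `flim_scene` objects sharing one geometry.
#' @export
simulate_timecourse <- function(spec, model = photophysics_model(), drift,
                                ph_sd = 0.15) {
  stopifnot(inherits(spec, "scene_spec"))
  drift <- as.data.frame(drift)
  if (!all(c("time_min", "mean_ph") %in% names(drift)))
    abort("`drift` needs columns `time_min` and `mean_ph`.")
  set.seed(spec$seed)
  placement <- place_vesicles(spec)
  scenes <- purrr::imap(drift$mean_ph, function(mu, i) {
    sp <- spec
    sp$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    set.seed(sp$seed + 1L)  # pH draws on their own stream, rendering on sp$seed
    ph_i <- rnorm(nrow(placement), mu, ph_sd)
    simulate_cell_scene(sp, model, placement = placement, ph_override = ph_i)
  })
  tibble(time_min = drift$time_min, mean_ph = drift$mean_ph, scene = scenes)
}
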