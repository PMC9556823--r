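# Synthetic TCSPC generators: every simulated photon is drawn from the
# wrapped bi-exponential arrival density implied by the photophysics model,
# then histogrammed exactly as a real acquisition would.

# inverse-CDF sample of an exponential wrapped into one laser period
sample_wrapped_exp <- function(n, tau, period) {
  -tau * log(1 - runif(n) * (1 - exp(-period / tau)))
}

sample_biexp_times <- function(n, decomp, period) {
  long <- runif(n) < decomp$f2
  t <- numeric(n)
  t[long] <- sample_wrapped_exp(sum(long), decomp$tau2, period)
  t[!long] <- sample_wrapped_exp(sum(!long), decomp$tau1, period)
  t
}

#' Simulate a uniform field of decay pixels at a fixed pH
#'
#' Generates a decay cube for a spatially uniform specimen (a calibration
#' well): each pixel's photon count is Poisson with the given mean, photon
#' arrival times are drawn from the bi-exponential mixture realising the
#' model's phasor target at `ph` (wrapped into one laser period, as photons
#' excited by earlier pulses fold into the recorded window), and arrivals
#' are histogrammed into `n_bins` bins.
#'
#' @param model A [photophysics_model()].
#' @param ph Programmed pH of the field.
#' @param dim Image size `c(height, width)`.
#' @param photons_per_pixel Mean photons per pixel (Poisson).
#' @param n_bins Number of histogram bins (default 128 over the full period).
#' @param rep_rate_mhz Laser repetition rate (default 80).
#' @param pixel_size_um Pixel size (default 0.133).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so composite generators can manage seeding).
#' @return A [decay_image()].
#' @examples
#' d <- simulate_decay_pixels(photophysics_model(), 6.0, dim = c(16, 16),
#'                            photons_per_pixel = 100, seed = 7)
#' sum(d$counts)
#' @export
simulate_decay_pixels <- function(model, ph, dim = c(32, 32),
                                  photons_per_pixel = 100, n_bins = 128,
                                  rep_rate_mhz = 80, pixel_size_um = 0.133,
                                  seed = NULL) {
  stopifnot(inherits(model, "photophysics_model"), length(dim) == 2)
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / rep_rate_mhz
  bin_width <- period / n_bins
  npix <- prod(dim)
  counts_px <- rpois(npix, photons_per_pixel)
  cube <- array(0L, dim = c(dim, n_bins))
  n <- sum(counts_px)
  if (n > 0) {
    decomp <- decompose_biexponential(model, ph, 2 * pi * rep_rate_mhz / 1000)
    t <- sample_biexp_times(n, decomp, period)
    bin <- pmin(floor(t / bin_width) + 1L, n_bins)
    pix <- rep.int(seq_len(npix), counts_px)
    cube <- array(tabulate(pix + (bin - 1L) * npix, nbins = npix * n_bins),
                  dim = c(dim, n_bins))
  }
  decay_image(cube, bin_width, rep_rate_mhz, pixel_size_um)
}

#' Simulate a pH calibration series of uniform wells
#'
#' Emulates the sensor calibration experiment: uniform wells spanning the
#' physiological pH range, imaged in independent replicates. Per-well photon
#' budgets are scaled by the model's relative emission intensity, so acidic
#' wells are dimmer exactly as the real sensor is. Returns the decay cubes
#' together with a programmed-truth table.
#'
#' @param model A [photophysics_model()].
#' @param ph_list pH values of the buffer series (default the 7.4-4.6 range
#'   in 0.4-0.5 steps).
#' @param replicates Independent replicates per pH (default 3).
#' @param dim Well image size (default 32 x 32).
#' @param photons_per_pixel Mean photons per pixel at the reference pH;
#'   scaled down with intensity at acidic pH.
#' @param n_bins Histogram bins (default 128).
#' @param seed Integer seed for the whole series.
#' @return A list with `wells` (tibble: `ph`, `replicate`, `decay`
#'   list-column, `total_photons`) and `truth` (tibble: `ph`, `tau_phase`,
#'   `g`, `s`, `intensity_rel`).
#' @export
simulate_calibration_series <- function(model,
                                        ph_list = c(7.4, 7.0, 6.5, 6.0, 5.5, 5.0, 4.6),
                                        replicates = 3, dim = c(32, 32),
                                        photons_per_pixel = 150, n_bins = 128,
                                        seed = 1L) {
  stopifnot(inherits(model, "photophysics_model"))
  set.seed(seed)
  grid <- tidyr::expand_grid(ph = ph_list, replicate = seq_len(replicates))
  wells <- grid |>
    dplyr::mutate(
      decay = purrr::map(.data$ph, function(p)
        simulate_decay_pixels(model, p, dim = dim,
                              photons_per_pixel = photons_per_pixel * model_intensity(model, p),
                              n_bins = n_bins)),
      total_photons = purrr::map_dbl(.data$decay, function(d) sum(d$counts)))
  truth <- tibble(ph = ph_list,
                  tau_phase = model_tau_phase(model, ph_list),
                  g = model_g(model, ph_list),
                  s = model_s(model, ph_list),
                  intensity_rel = model_intensity(model, ph_list))
  list(wells = wells, truth = truth)
}

#' Well intensities of a simulated calibration series
#'
#' Collapses a [simulate_calibration_series()] result to the (pH, intensity)
#' table used for the intensity calibration: total detected photons per well.
#'
#' @param series A [simulate_calibration_series()] result.
#' @return Tibble with columns `ph`, `replicate`, `intensity`.
#' @export
calibration_series_intensity <- function(series) {
  series$wells |>
    dplyr::transmute(.data$ph, .data$replicate, intensity = .data$total_photons)
}

#' Simulate a plate-style intensity calibration
#'
#' Emulates the emission-intensity calibration measurement: mean well
#' intensity proportional to the model's 4PL response, with a constant
#' *absolute* measurement noise (the defining property of intensity
#' readouts — the error does not shrink as the signal drops toward the
#' acidic plateau, so the *relative* error explodes there).
#'
#' @param model A [photophysics_model()].
#' @param ph_list Buffer pH values.
#' @param replicates Independent replicates per pH (default 3).
#' @param noise_sd Absolute measurement noise, as a fraction of the
#'   reference-pH intensity (default 0.02).
#' @param seed Integer seed.
#' @return Tibble with columns `ph`, `replicate`, `intensity` (normalised
#'   units, reference pH = 1 on average).
#' @export
simulate_intensity_calibration <- function(model,
                                           ph_list = c(7.4, 7.0, 6.5, 6.0, 5.5, 5.0, 4.6),
                                           replicates = 3, noise_sd = 0.02,
                                           seed = 1L) {
  stopifnot(inherits(model, "photophysics_model"))
  set.seed(seed)
  tidyr::expand_grid(ph = ph_list, replicate = seq_len(replicates)) |>
    dplyr::mutate(intensity = model_intensity(model, .data$ph) +
                    rnorm(dplyr::n(), 0, noise_sd))
}

#' Phasor summary of a simulated calibration series
#'
#' Runs the standard analysis over every well — spatial binning, per-pixel
#' phasor, photon threshold, photon-weighted G and phase-lifetime means —
#' and averages replicates, yielding the (pH, G) table a G calibration is
#' fitted to.
#'
#' @param series A [simulate_calibration_series()] result.
#' @param bin_factor Spatial bin applied before the phasor transform
#'   (default 8).
#' @param min_photons Photon threshold after binning (default 15).
#' @return Tibble with one row per well: `ph`, `replicate`, `g`, `tau`,
#'   `total_photons`.
#' @export
calibration_series_phasor <- function(series, bin_factor = 8, min_photons = 15) {
  series$wells |>
    dplyr::mutate(purrr::map_dfr(.data$decay, function(d) {
      ph_img <- threshold_photons(compute_phasor(spatial_bin(d, bin_factor)),
                                  min_photons)
      tibble(g = image_weighted_G(ph_img),
             tau = image_weighted_lifetime(compute_fast_lifetime(ph_img)))
    })) |>
    dplyr::select("ph", "replicate", "g", "tau", "total_photons")
}
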