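#' Time-resolved FLIM decay cube
#'
#' A `decay_image` holds a per-pixel photon-arrival histogram cube — the raw
#' product of time-correlated single-photon counting (TCSPC) — together with
#' the acquisition metadata needed to interpret it: the histogram bin width,
#' the laser repetition rate (which sets the period and the phasor angular
#' frequency), and the pixel size.
#'
#' @param counts Non-negative integer array of shape `height x width x n_bins`
#'   (photons per pixel per time bin). A `height x width` matrix is accepted
#'   for a single-bin cube.
#' @param bin_width_ns Width of one time bin, in nanoseconds.
#' @param rep_rate_mhz Laser repetition rate in MHz (default 80, pulsed
#'   excitation at 12.5 ns period).
#' @param pixel_size_um Lateral pixel size in micrometres (default 0.133).
#' @param channel_name Name of the detection channel (default `"mApple"`).
#'
#' @details
#' The histogram must fit inside one laser period: `n_bins * bin_width_ns`
#' may not exceed `1000 / rep_rate_mhz` ns. Photons from earlier pulses fold
#' into the recorded window (see [simulate_decay_pixels()]), so the cube is a
#' complete description of the periodic decay.
#'
#' @return An object of class `decay_image` with elements `counts`,
#'   `bin_width`, `rep_rate`, `pixel_size`, `channel`.
#' @seealso [compute_phasor()], [spatial_bin()], [read_decay_tiff()]
#' @examples
#' cube <- array(rpois(4 * 4 * 16, 5), dim = c(4, 4, 16))
#' d <- decay_image(cube, bin_width_ns = 12.5 / 16)
#' d
#' @export
decay_image <- function(counts, bin_width_ns, rep_rate_mhz = 80,
                        pixel_size_um = 0.133, channel_name = "mApple") {
  if (is.matrix(counts)) counts <- array(counts, dim = c(dim(counts), 1L))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    abort("`counts` must be a height x width x n_bins array.")
  if (length(counts) == 0L) abort("`counts` is empty: the decay cube has no pixels or bins.")
  if (anyNA(counts) || any(counts < 0))
    abort("`counts` must be non-negative and free of NA.")
  if (!is.numeric(bin_width_ns) || length(bin_width_ns) != 1L || bin_width_ns <= 0)
    abort("`bin_width_ns` must be a single positive number.")
  if (rep_rate_mhz <= 0) abort("`rep_rate_mhz` must be positive.")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  period <- 1000 / rep_rate_mhz
  span <- dim(counts)[3] * bin_width_ns
  if (span > period * (1 + 1e-9))
    abort(sprintf(
      "`bin_width_ns`: n_bins * bin_width (%.4f ns) exceeds the laser period %.4f ns (rep_rate %.1f MHz).",
      span, period, rep_rate_mhz))
  structure(
    list(counts = counts, bin_width = bin_width_ns, rep_rate = rep_rate_mhz,
         pixel_size = pixel_size_um, channel = channel_name),
    class = "decay_image")
}

#' @export
print.decay_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_image> %d x %d px, %d bins of %.4g ns (%s, %.0f MHz, %.3f um/px), %s photons\n",
    d[1], d[2], d[3], x$bin_width, x$channel, x$rep_rate, x$pixel_size,
    format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.decay_image <- function(x) dim(x$counts)

#' Laser period and phasor angular frequency of a decay cube
#'
#' @param decay A [decay_image()].
#' @return `decay_period()` the laser period in ns; `decay_omega()` the
#'   first-harmonic angular frequency `2 * pi * rep_rate` in rad/ns.
#' @export
decay_period <- function(decay) 1000 / decay$rep_rate

#' @rdname decay_period
#' @export
decay_omega <- function(decay) 2 * pi * decay$rep_rate / 1000

#' Spatially bin a decay cube
#'
#' Sums decay histograms over non-overlapping `factor x factor` pixel blocks,
#' the standard pre-processing applied to uniform calibration wells before
#' phasor extraction. The pixel size is multiplied by `factor` and photons
#' are conserved over the retained area. Edges that do not fill a complete
#' block are cropped (with a message).
#'
#' @param decay A [decay_image()].
#' @param factor Positive integer block edge (default 8).
#' @return A [decay_image()] of size `floor(h/factor) x floor(w/factor)`.
#' @examples
#' cube <- array(1L, dim = c(16, 16, 4))
#' b <- spatial_bin(decay_image(cube, 1), factor = 8)
#' dim(b)          # 2 x 2 x 4
#' b$counts[1, 1, 1]  # 64 pixels pooled
#' @export
spatial_bin <- function(decay, factor = 8) {
  stopifnot(inherits(decay, "decay_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) abort("`factor` must be a positive integer.")
  if (factor == 1L) return(decay)
  d <- dim(decay$counts)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  if (h2 < 1L || w2 < 1L)
    abort(sprintf("`factor` (%d) exceeds the image size %d x %d.", factor, d[1], d[2]))
  ch <- h2 * factor; cw <- w2 * factor
  if (ch < d[1] || cw < d[2])
    message(sprintf("spatial_bin: cropping %d row(s) and %d column(s) to fit %dx%d blocks.",
                    d[1] - ch, d[2] - cw, factor, factor))
  x <- decay$counts[seq_len(ch), seq_len(cw), , drop = FALSE]
  # collapse factor-blocks: reshape to (factor, h2, factor, w2, nb), sum dims 1 & 3
  dim(x) <- c(factor, h2, factor, w2, d[3])
  out <- colSums(aperm(x, c(1, 3, 2, 4, 5)), dims = 2)
  decay_image(out, decay$bin_width, decay$rep_rate,
              decay$pixel_size * factor, decay$channel)
}
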