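#' Convert an RGB image to grayscale luminance
#'
#' Uses the ITU-R BT.601 luma weights 0.299 R + 0.587 G + 0.114 B, the
#' standard broadcast luminance transform. Values keep the scale of the
#' input (0-255 for 8-bit images).
#'
#' @param image H x W x 3 numeric array of channel values.
#' @return H x W numeric matrix of luminance values.
#' @export
#' @examples
#' img <- array(255, dim = c(4, 4, 3))
#' to_grayscale(img)[1, 1]  # 255
to_grayscale <- function(image) {
  check_rgb_array(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Two-dimensional discrete Fourier spectrum of a grayscale image
#'
#' Computes F(u,v) = sum_m sum_n f(m,n) exp(-j 2 pi (u m / H + v n / W)),
#' the unnormalized forward 2-D DFT, with the real and imaginary planes kept
#' separate so they can be fed to a convolutional network as two channels.
#'
#' @param gray H x W numeric matrix (H, W >= 2), all values finite.
#' @return An object of class `spectrum_plane`: list with `real` and `imag`
#'   H x W matrices.
#' @export
dft2 <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 2L || ncol(gray) < 2L)
    stop("`gray` must be a numeric matrix of size at least 2 x 2", call. = FALSE)
  if (!all(is.finite(gray)))
    stop("`gray` contains non-finite values", call. = FALSE)
  f <- stats::fft(gray)
  structure(list(real = Re(f), imag = Im(f)), class = "spectrum_plane")
}

#' @export
print.spectrum_plane <- function(x, ...) {
  cat(sprintf("<spectrum_plane %d x %d, DC = %.4g>\n",
              nrow(x$real), ncol(x$real), x$real[1, 1]))
  invisible(x)
}

spectrum_magnitude <- function(spectrum) {
  sqrt(spectrum$real^2 + spectrum$imag^2)
}

# Centered frequency coordinate for indices 0..n-1: ((u + n/2) mod n) - n/2
centered_freq <- function(n) {
  u <- seq_len(n) - 1L
  ((u + n %/% 2L) %% n) - n %/% 2L
}

#' High/low frequency intensity of a Fourier spectrum
#'
#' Splits spectral magnitudes by centred radial distance from the DC
#' component. The high band is the mean magnitude at radii at or beyond
#' `cutoff_fraction` of the maximum radius; the low band is the mean over the
#' complement (which contains DC). Wrinkled, strongly dried leaves show
#' elevated high-band intensity; the statistic tracks drying degree.
#'
#' @param spectrum a `spectrum_plane` from [dft2()].
#' @param cutoff_fraction radial cutoff as a fraction of the maximum radius,
#'   in (0, 1). Default 0.25.
#' @return list with fields `high`, `low` and `cutoff_fraction`.
#' @export
frequency_intensity <- function(spectrum, cutoff_fraction = 0.25) {
  check_number(cutoff_fraction, "cutoff_fraction")
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1)
    abort_field("cutoff_fraction", "must lie strictly between 0 and 1")
  mag <- spectrum_magnitude(spectrum)
  h <- nrow(mag); w <- ncol(mag)
  if (h < 2L || w < 2L)
    stop("degenerate spectrum: need at least 2 x 2", call. = FALSE)
  fu <- centered_freq(h)
  fv <- centered_freq(w)
  r <- sqrt(outer(fu^2, fv^2, `+`))
  r_max <- max(r)
  high_mask <- r >= cutoff_fraction * r_max
  list(high = mean(mag[high_mask]),
       low = mean(mag[!high_mask]),
       cutoff_fraction = cutoff_fraction)
}

#' Min-max normalize a series of intensity values to [0, 1]
#'
#' Used to place per-degree mean high/low frequency intensities of a dataset
#' on a common 0-1 scale for plotting the drying trend.
#'
#' @param x numeric vector.
#' @return numeric vector in [0, 1]; all-equal input maps to 0.
#' @export
normalize_series <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-drying-degree frequency intensity statistics of a dataset
#'
#' Computes the mean high- and low-frequency intensity of the grayscale
#' spectra of a set of images grouped by drying degree, plus min-max
#' normalized versions of both series.
#'
#' @param images list of H x W x 3 arrays (0-255).
#' @param drying integer vector of drying degrees, one per image.
#' @param cutoff_fraction radial cutoff, see [frequency_intensity()].
#' @return data.frame with columns `degree`, `mean_high`, `mean_low`,
#'   `norm_high`, `norm_low`, one row per distinct degree (sorted).
#' @export
frequency_intensity_by_degree <- function(images, drying,
                                          cutoff_fraction = 0.25) {
  stopifnot(length(images) == length(drying))
  hi <- vapply(images, function(im) {
    frequency_intensity(dft2(to_grayscale(im)), cutoff_fraction)$high
  }, numeric(1))
  lo <- vapply(images, function(im) {
    frequency_intensity(dft2(to_grayscale(im)), cutoff_fraction)$low
  }, numeric(1))
  degs <- sort(unique(drying))
  mh <- vapply(degs, function(d) mean(hi[drying == d]), numeric(1))
  ml <- vapply(degs, function(d) mean(lo[drying == d]), numeric(1))
  data.frame(degree = degs, mean_high = mh, mean_low = ml,
             norm_high = normalize_series(mh), norm_low = normalize_series(ml))
}

#' Stack a spectrum into the 2-channel network input
#'
#' Real and imaginary planes become separate channels under a
#' sign-preserving log compression, `sign(z) * log1p(|z|)`. Spectra of
#' natural images span several decades (the DC term dwarfs the sparse
#' texture peaks that carry the drying signal); the compression places both
#' on a single activation scale so the convolutional branch sees, and can
#' propagate gradient through, the high-frequency structure.
#'
#' @param spectrum a `spectrum_plane`.
#' @return H x W x 2 numeric array.
#' @export
spectrum_channels <- function(spectrum) {
  h <- nrow(spectrum$real); w <- ncol(spectrum$real)
  out <- array(0, dim = c(h, w, 2))
  out[, , 1] <- sign(spectrum$real) * log1p(abs(spectrum$real))
  out[, , 2] <- sign(spectrum$imag) * log1p(abs(spectrum$imag))
  out
}
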