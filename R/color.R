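#' Center-crop an image
#'
#' Keeps the centred `crop_fraction * H` by `crop_fraction * W` window
#' (floored sizes, centred by integer division). The centre of a barn image
#' is dominated by densely racked leaves, so cropping suppresses peripheral
#' noise colours before the histogram is built.
#'
#' @param image H x W x 3 numeric array.
#' @param crop_fraction fraction of each side to keep, in (0, 1].
#' @return cropped H' x W' x 3 array.
#' @export
center_crop <- function(image, crop_fraction = 0.6) {
  check_rgb_array(image)
  check_number(crop_fraction, "crop_fraction")
  if (crop_fraction <= 0 || crop_fraction > 1)
    abort_field("crop_fraction", "must lie in (0, 1]")
  h <- dim(image)[1]; w <- dim(image)[2]
  h2 <- floor(crop_fraction * h); w2 <- floor(crop_fraction * w)
  if (h2 < 8L || w2 < 8L)
    stop("center crop smaller than 8 x 8 pixels", call. = FALSE)
  top <- (h - h2) %/% 2L
  left <- (w - w2) %/% 2L
  image[(top + 1L):(top + h2), (left + 1L):(left + w2), , drop = FALSE]
}

#' Uniformly quantize the colour space of an 8-bit image
#'
#' Each channel value v in 0..255 is mapped to the level
#' `floor(v * q_levels / 256)`, giving at most `q_levels^3` distinct colours.
#'
#' @param image H x W x 3 array with 8-bit channel values (0-255).
#' @param q_levels levels per channel, integer >= 2. 4 is the tuned default.
#' @return H x W x 3 integer array of level indices in 0..q_levels-1, with
#'   attribute `q_levels`.
#' @export
quantize_colors <- function(image, q_levels = 4L) {
  check_rgb_array(image)
  check_number(q_levels, "q_levels", lo = 2, integer = TRUE)
  if (any(image < 0 | image > 255))
    abort_field("image", "channel values must lie in [0, 255]")
  q <- array(floor(image * q_levels / 256), dim = dim(image))
  storage.mode(q) <- "integer"
  attr(q, "q_levels") <- as.integer(q_levels)
  q
}

#' Descriptor of the most common quantized colours
#'
#' Builds the colour histogram of a quantized image, keeps the `k_colors`
#' most frequent colours, and records for each its quantized RGB triple, its
#' relative frequency and the raster-order position (row-major, top-left
#' first) at which it first appears. Frequency ties are broken by smaller
#' first-appearance rank, then by lexicographic (R, G, B) triple, so the
#' descriptor is fully deterministic. When fewer than `k_colors` distinct
#' colours exist the remaining slots are padding, flagged in `pad_mask`.
#'
#' @param quantized output of [quantize_colors()].
#' @param k_colors number of colours to retain, integer >= 1. 20 is the
#'   tuned default.
#' @return An object of class `common_color_descriptor`: list with `colors`
#'   (k x 3 integer matrix), `frequency` (length k), `first_rank` (length k,
#'   1-based raster index of first appearance), `pad_mask` (logical, TRUE
#'   for real entries), `q_levels`, `n_pixels`.
#' @export
common_color_descriptor <- function(quantized, k_colors = 20L) {
  check_rgb_array(quantized)
  check_number(k_colors, "k_colors", lo = 1, integer = TRUE)
  q <- attr(quantized, "q_levels")
  if (is.null(q)) q <- max(quantized) + 1L
  h <- dim(quantized)[1]; w <- dim(quantized)[2]
  n <- h * w
  if (n < 1L) stop("empty image", call. = FALSE)
  # row-major raster order: row 1 left-to-right, then row 2, ...
  r <- t(quantized[, , 1]); g <- t(quantized[, , 2]); b <- t(quantized[, , 3])
  code <- as.vector(r) * q * q + as.vector(g) * q + as.vector(b)
  first <- !duplicated(code)
  keys <- code[first]
  first_rank <- which(first)
  counts <- tabulate(match(code, keys), nbins = length(keys))
  # order: frequency desc, then first appearance asc, then lexicographic code
  ord <- order(-counts, first_rank, keys)
  k_real <- min(k_colors, length(keys))
  take <- ord[seq_len(k_real)]
  colors <- matrix(0L, nrow = k_colors, ncol = 3,
                   dimnames = list(NULL, c("r", "g", "b")))
  kk <- keys[take]
  colors[seq_len(k_real), 1] <- kk %/% (q * q)
  colors[seq_len(k_real), 2] <- (kk %/% q) %% q
  colors[seq_len(k_real), 3] <- kk %% q
  freq <- numeric(k_colors)
  freq[seq_len(k_real)] <- counts[take] / n
  rank1 <- numeric(k_colors)
  rank1[seq_len(k_real)] <- first_rank[take]
  structure(list(colors = colors, frequency = freq, first_rank = rank1,
                 pad_mask = seq_len(k_colors) <= k_real,
                 q_levels = as.integer(q), n_pixels = n),
            class = "common_color_descriptor")
}

#' @export
print.common_color_descriptor <- function(x, ...) {
  k <- sum(x$pad_mask)
  cat(sprintf("<common_color_descriptor: %d/%d colours, Q = %d>\n",
              k, length(x$pad_mask), x$q_levels))
  top <- min(k, 5L)
  for (i in seq_len(top))
    cat(sprintf("  (%d,%d,%d) freq %.3f first at %d\n",
                x$colors[i, 1], x$colors[i, 2], x$colors[i, 3],
                x$frequency[i], x$first_rank[i]))
  invisible(x)
}

#' Serialize a colour descriptor to the fixed-length network input
#'
#' Per slot: the three colour levels scaled to [0, 1], the relative
#' frequency, and the first-appearance rank normalized by the pixel count.
#' Padded slots are all-zero.
#'
#' @param descriptor a `common_color_descriptor`.
#' @return numeric vector of length `5 * k_colors`.
#' @export
descriptor_vector <- function(descriptor) {
  k <- length(descriptor$pad_mask)
  q <- descriptor$q_levels
  m <- cbind(descriptor$colors / max(q - 1L, 1L),
             descriptor$frequency,
             descriptor$first_rank / descriptor$n_pixels)
  m[!descriptor$pad_mask, ] <- 0
  as.vector(t(m))
}

#' Mask of pixels whose colour was retained by the descriptor
#'
#' Marks every pixel of the quantized image whose colour is one of the
#' retained common colours; on barn imagery the retained colours concentrate
#' on the leaves rather than the background.
#'
#' @param quantized output of [quantize_colors()].
#' @param descriptor a `common_color_descriptor` computed from it.
#' @return H x W logical matrix.
#' @export
retained_color_mask <- function(quantized, descriptor) {
  q <- descriptor$q_levels
  code <- quantized[, , 1] * q * q + quantized[, , 2] * q + quantized[, , 3]
  keep <- descriptor$colors[descriptor$pad_mask, , drop = FALSE]
  keys <- keep[, 1] * q * q + keep[, 2] * q + keep[, 3]
  matrix(code %in% keys, nrow = dim(quantized)[1])
}

#' Export a colour descriptor as JSON
#'
#' @param descriptor a `common_color_descriptor`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_descriptor_json <- function(descriptor, path) {
  real <- descriptor$pad_mask
  obj <- list(q_levels = descriptor$q_levels,
              colors = descriptor$colors[real, , drop = FALSE],
              frequency = descriptor$frequency[real],
              first_rank = descriptor$first_rank[real])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Full CCFM preprocessing: crop -> quantize -> descriptor -> vector
ccfm_input <- function(image, config) {
  crop <- center_crop(image, config$crop_fraction)
  qimg <- quantize_colors(crop, config$q_levels)
  descriptor_vector(common_color_descriptor(qimg, config$k_colors))
}
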