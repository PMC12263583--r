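# Class counts of the three ordinal states: yellowing 0-6, browning 0-5,
# drying 0-8.
N_YELLOWING <- 7L
N_BROWNING <- 6L
N_DRYING <- 9L

# Nominal browning bins by brown leaf-area fraction. Edges at exactly 10%,
# 20%, 30%, 50% follow the left-closed/right-open convention (a cover of
# exactly 0.10 is class 2).
BROWNING_BREAKS <- c(0, 0.10, 0.20, 0.30, 0.50)

# Sampling margins inside each bin so that pixel rounding can never move a
# planted cover across a bin edge.
BROWNING_DRAW <- list(c(0, 0), c(0.008, 0.092), c(0.108, 0.192),
                      c(0.208, 0.292), c(0.308, 0.492), c(0.508, 0.66))

# Colour band (0-255 per channel) that identifies planted brown pixels under
# the generator's default noise, wrinkle and jitter budget.
BROWN_BAND <- list(r = c(145, 235), g = c(81, 161), b = c(80, 160))

# Near-isoluminant palette (BT.601 luma ~ 140 for every surface): state
# classes are encoded in chrominance while luminance carries the wrinkle
# texture, so the colour branch reads hue and the spectral branch reads
# drying, with minimal cross-talk from region edges.
PALETTE <- list(
  background = c(120, 140, 200),
  brown = c(188, 120, 120),
  vein_green = c(60, 180, 60),
  vein_white = c(150, 150, 215),
  vein_purple = c(200, 90, 220),
  green_base = c(90, 170, 20))

# leaf body colour: green -> yellow as yellow_fraction rises, luma constant
leaf_color <- function(yf) c(80 + 130 * yf, 194 - 66.2 * yf, 20)

#' Ordinal state label of a curing tobacco leaf
#'
#' A triple of class indices: yellowing degree in 0-6, browning degree in
#' 0-5 (binned by brown leaf-area percentage), drying degree in 0-8.
#'
#' @param yellowing integer in 0..6.
#' @param browning integer in 0..5.
#' @param drying integer in 0..8.
#' @return object of class `state_label`.
#' @export
#' @examples
#' state_label(2, 0, 4)
state_label <- function(yellowing, browning, drying) {
  check_number(yellowing, "yellowing", 0, N_YELLOWING - 1L, integer = TRUE)
  check_number(browning, "browning", 0, N_BROWNING - 1L, integer = TRUE)
  check_number(drying, "drying", 0, N_DRYING - 1L, integer = TRUE)
  structure(list(yellowing = as.integer(yellowing),
                 browning = as.integer(browning),
                 drying = as.integer(drying)),
            class = "state_label")
}

#' @export
print.state_label <- function(x, ...) {
  cat(sprintf("<state_label yellowing=%d browning=%d drying=%d>\n",
              x$yellowing, x$browning, x$drying))
  invisible(x)
}

#' Browning class of a brown-cover fraction
#'
#' Bins: 0 = exactly 0, 1 = (0, 0.10), 2 = [0.10, 0.20), 3 = [0.20, 0.30),
#' 4 = [0.30, 0.50), 5 = at or above 0.50.
#'
#' @param cover brown leaf-area fraction in [0, 1].
#' @return integer class in 0..5.
#' @export
browning_bin <- function(cover) {
  check_number(cover, "cover", 0, 1)
  if (cover == 0) return(0L)
  as.integer(findInterval(cover, BROWNING_BREAKS[-1], left.open = FALSE) + 1L)
}

#' Synthesis parameters for one labelled leaf image
#'
#' Draws the continuous rendering parameters consistently with a state
#' label: `yellow_fraction` rises monotonically with the yellowing class,
#' `brown_cover` is drawn inside the browning class's area bin, and wrinkle
#' amplitude/frequency rise with the drying class (dried leaves wrinkle,
#' which raises the high-frequency content of the image spectrum).
#'
#' @param label a [state_label()].
#' @param height,width image size in pixels, at least 32.
#' @param background_noise_sd Gaussian noise sd on background pixels.
#' @param seed integer seed; the rendered image is a pure function of the
#'   spec including this seed.
#' @return object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(label, height = 64L, width = 64L,
                           background_noise_sd = 2, seed = 1L) {
  stopifnot(inherits(label, "state_label"))
  check_number(height, "height", 32, integer = TRUE)
  check_number(width, "width", 32, integer = TRUE)
  check_number(background_noise_sd, "background_noise_sd", 0)
  check_number(seed, "seed", integer = TRUE)
  withr::with_seed(as.integer((as.numeric(seed) * 7919) %% 2147483629), {
    yf <- (label$yellowing + runif(1, 0, 0.8)) / N_YELLOWING
    bd <- BROWNING_DRAW[[label$browning + 1L]]
    cover <- runif(1, bd[1], bd[2])
    amp <- 2.4 * label$drying + runif(1, 0, 0.8)
    freq <- 0.22 + 0.01 * label$drying + runif(1, 0, 0.004)
  })
  new_synthesis_spec(label, height, width, yf, cover, amp, freq,
                     background_noise_sd, seed)
}

#' Construct a synthesis spec from explicit rendering parameters
#'
#' Low-level constructor used when the continuous parameters are chosen by
#' hand (e.g. to sweep wrinkle amplitude at fixed seed). Validates every
#' field and checks that `brown_cover` lies inside the browning class's bin.
#'
#' @param label a [state_label()].
#' @param height,width image size in pixels.
#' @param yellow_fraction real in [0, 1].
#' @param brown_cover real in [0, 1], inside the bin of `label$browning`.
#' @param wrinkle_amplitude non-negative luminance amplitude of the ridges.
#' @param wrinkle_frequency ridge frequency in cycles per pixel.
#' @param background_noise_sd Gaussian noise sd on background pixels.
#' @param seed integer seed.
#' @return object of class `synthesis_spec`.
#' @export
new_synthesis_spec <- function(label, height = 64L, width = 64L,
                               yellow_fraction = 0.5, brown_cover = 0,
                               wrinkle_amplitude = 0,
                               wrinkle_frequency = 0.25,
                               background_noise_sd = 2, seed = 1L) {
  stopifnot(inherits(label, "state_label"))
  check_number(height, "height", 32, integer = TRUE)
  check_number(width, "width", 32, integer = TRUE)
  check_number(yellow_fraction, "yellow_fraction", 0, 1)
  check_number(brown_cover, "brown_cover", 0, 1)
  check_number(wrinkle_amplitude, "wrinkle_amplitude", 0)
  check_number(wrinkle_frequency, "wrinkle_frequency", 0)
  check_number(background_noise_sd, "background_noise_sd", 0)
  check_number(seed, "seed", integer = TRUE)
  if (browning_bin(brown_cover) != label$browning)
    abort_field("brown_cover",
                sprintf("%.4f lies in browning bin %d, label says %d",
                        brown_cover, browning_bin(brown_cover),
                        label$browning))
  structure(list(label = label, height = as.integer(height),
                 width = as.integer(width),
                 yellow_fraction = yellow_fraction,
                 brown_cover = brown_cover,
                 wrinkle_amplitude = wrinkle_amplitude,
                 wrinkle_frequency = wrinkle_frequency,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synthesis_spec")
}

# Elliptical leaf support mask covering ~75% of the frame.
leaf_mask <- function(h, w) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ((y - cy) / (0.49 * h))^2 + ((x - cx) / (0.49 * w))^2 <= 1
}

#' Render a labelled synthetic leaf image
#'
#' Produces an 8-bit RGB image whose appearance encodes the label: the leaf
#' colour interpolates green to yellow with `yellow_fraction` (with the
#' midrib whitening then purpling for yellowing classes 4-6, a synthetic
#' proxy for the vein-centric class definitions); exactly
#' `round(brown_cover * H * W)` pixels are painted in the brown band as
#' clustered blotches; and oriented sinusoidal ridges of amplitude
#' `wrinkle_amplitude` emulate drying wrinkles, raising the high-frequency
#' intensity of the spectrum monotonically with amplitude. Deterministic
#' given the spec (including its seed).
#'
#' @param spec a [synthesis_spec()] or [new_synthesis_spec()].
#' @return object of class `labeled_image`: list with `pixels`
#'   (H x W x 3 integer array, 0-255), `label`, `metadata`.
#' @export
generate_leaf_image <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  h <- spec$height; w <- spec$width
  withr::with_seed(spec$seed, {
    # fixed-count draws first so parameter sweeps at a fixed seed reuse the
    # same noise realisation
    leaf_jitter <- runif(3, -6, 6)
    brown_jitter <- runif(3, -3, 3)
    theta <- runif(2, 0, 2 * pi)
    phase <- runif(2, 0, 2 * pi)
    wiggle_amp <- runif(1, 0.5, 1.5)
    wiggle_phase <- runif(1, 0, 2 * pi)
    leaf_noise <- matrix(rnorm(h * w, 0, 1.5), h, w)
    bg_noise <- array(rnorm(h * w * 3, 0, spec$background_noise_sd),
                      dim = c(h, w, 3))

    mask <- leaf_mask(h, w)
    yf <- spec$yellow_fraction
    leaf_col <- leaf_color(yf) + leaf_jitter

    px <- array(0, dim = c(h, w, 3))
    bg_col <- PALETTE$background
    for (c in 1:3) {
      plane <- matrix(bg_col[c], h, w) + bg_noise[, , c]
      plane[mask] <- leaf_col[c]
      px[, , c] <- plane
    }

    # midrib: vertical wiggly strip; colour encodes yellowing classes 4-6
    yl <- spec$label$yellowing
    vein_w <- max(2L, round(w / 21))
    cx <- (w + 1) / 2 + wiggle_amp *
      sin(2 * pi * seq_len(h) / h + wiggle_phase)
    vein <- matrix(FALSE, h, w)
    for (r in seq_len(h)) {
      lo <- max(1L, round(cx[r] - vein_w / 2))
      hi <- min(w, round(cx[r] + vein_w / 2))
      vein[r, lo:hi] <- TRUE
    }
    vein <- vein & mask
    vein_col <- matrix(rep(PALETTE$vein_green, each = h * w), ncol = 3)
    if (yl == 4L) {
      vein_col <- matrix(rep(PALETTE$vein_white, each = h * w), ncol = 3)
    } else if (yl == 5L) {
      top <- as.vector(row(matrix(0, h, w)) <= h / 2)
      vein_col <- matrix(rep(PALETTE$vein_purple, each = h * w), ncol = 3)
      vein_col[top, ] <- rep(PALETTE$vein_white, each = sum(top))
    } else if (yl == 6L) {
      vein_col <- matrix(rep(PALETTE$vein_purple, each = h * w), ncol = 3)
    }
    for (c in 1:3) {
      plane <- px[, , c]
      plane[vein] <- vein_col[as.vector(vein), c][seq_len(sum(vein))]
      px[, , c] <- plane
    }
    # yellowing class 2: green base band at the bottom of the leaf
    if (yl == 2L) {
      base_rows <- seq.int(floor(0.88 * h), h)
      gb <- PALETTE$green_base
      for (c in 1:3) {
        plane <- px[, , c]
        sel <- mask
        sel[-base_rows, ] <- FALSE
        plane[sel] <- gb[c]
        px[, , c] <- plane
      }
    }

    # brown blotches: exactly round(cover * H * W) pixels, grown from random
    # nuclei inside the leaf, avoiding the midrib
    m <- round(spec$brown_cover * h * w)
    if (m > 0) {
      cand <- which(mask & !vein)
      if (length(cand) < m) cand <- which(mask)
      n_seed <- max(1L, round(m / (0.15 * h * w)))
      nuclei <- sample(cand, min(n_seed, length(cand)))
      cy <- (cand - 1L) %% h + 1L
      cxx <- (cand - 1L) %/% h + 1L
      ny <- (nuclei - 1L) %% h + 1L
      nx <- (nuclei - 1L) %/% h + 1L
      d2 <- rep(Inf, length(cand))
      for (k in seq_along(nuclei))
        d2 <- pmin(d2, (cy - ny[k])^2 + (cxx - nx[k])^2)
      d2 <- d2 + runif(length(cand), 0, 2)
      brown_idx <- cand[order(d2)[seq_len(m)]]
      bc <- PALETTE$brown + brown_jitter
      for (c in 1:3) {
        plane <- px[, , c]
        plane[brown_idx] <- bc[c]
        px[, , c] <- plane
      }
    }

    # drying wrinkles: two oriented sinusoidal ridge systems on the leaf
    y <- matrix(seq_len(h), h, w)
    x <- matrix(seq_len(w), h, w, byrow = TRUE)
    amp <- spec$wrinkle_amplitude
    f1 <- spec$wrinkle_frequency
    wr <- amp * sin(2 * pi * f1 * (x * cos(theta[1]) + y * sin(theta[1])) +
                      phase[1]) +
      0.5 * amp * sin(2 * pi * f1 * 1.37 *
                        (x * cos(theta[2]) + y * sin(theta[2])) + phase[2])
    wr[!mask] <- 0
    lum <- wr + leaf_noise * mask
    for (c in 1:3) px[, , c] <- px[, , c] + lum

    pixels <- array(as.integer(clip255(px)), dim = c(h, w, 3))
  })
  structure(list(pixels = pixels, label = spec$label,
                 metadata = list(seed = spec$seed)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image %d x %d, yellowing=%d browning=%d drying=%d>\n",
              d[1], d[2], x$label$yellowing, x$label$browning,
              x$label$drying))
  invisible(x)
}

#' Mask of pixels inside the planted brown colour band
#'
#' @param image a `labeled_image` or an H x W x 3 array (0-255).
#' @return H x W logical matrix.
#' @export
brown_band_mask <- function(image) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  check_rgb_array(px)
  px[, , 1] >= BROWN_BAND$r[1] & px[, , 1] <= BROWN_BAND$r[2] &
    px[, , 2] >= BROWN_BAND$g[1] & px[, , 2] <= BROWN_BAND$g[2] &
    px[, , 3] >= BROWN_BAND$b[1] & px[, , 3] <= BROWN_BAND$b[2]
}

# Joint label sampling: Gaussian copula with positive association between
# yellowing and drying (leaves dry as they yellow) and a weaker link to
# browning; marginals follow the requested per-state weights.
sample_state_labels <- function(n, class_balance, correlation) {
  sigma <- diag(3)
  sigma[1, 2] <- sigma[2, 1] <- correlation["yb"]
  sigma[1, 3] <- sigma[3, 1] <- correlation["yd"]
  sigma[2, 3] <- sigma[3, 2] <- correlation["bd"]
  l <- chol(sigma)
  z <- matrix(rnorm(3 * n), n, 3) %*% l
  u <- pnorm(z)
  pick <- function(uu, w) {
    p <- cumsum(w) / sum(w)
    findInterval(uu, p, left.open = TRUE)
  }
  data.frame(yellowing = pick(u[, 1], class_balance$yellowing),
             browning = pick(u[, 2], class_balance$browning),
             drying = pick(u[, 3], class_balance$drying),
             progress = rowMeans(u))
}

#' Generate a labelled synthetic leaf-image dataset on disk
#'
#' Draws `n` state labels jointly (Gaussian copula: yellowing and drying
#' strongly positively associated, browning weakly, marginals following
#' `class_balance`), renders each image, writes PNG files plus a CSV
#' manifest with columns `image_path, yellowing, browning, drying, area,
#' timestamp, temperature, humidity`. Temperature rises and humidity falls
#' with the latent curing progress, mirroring a bulk-curing schedule sampled
#' at 10-minute intervals.
#'
#' @param n number of images, >= 1.
#' @param class_balance list with non-negative weight vectors `yellowing`
#'   (length 7), `browning` (6), `drying` (9); default uniform.
#' @param seed integer seed; the dataset is reproducible from it.
#' @param out_dir output directory (created if missing).
#' @param height,width image size in pixels.
#' @param background_noise_sd background noise level.
#' @param correlation named vector of copula correlations `yd`, `yb`, `bd`.
#' @return path of the written manifest CSV.
#' @export
generate_dataset <- function(n, class_balance = NULL, seed = 1L,
                             out_dir = tempfile("leafset"),
                             height = 64L, width = 64L,
                             background_noise_sd = 2,
                             correlation = c(yd = 0.8, yb = 0.35, bd = 0.35)) {
  check_number(n, "n", 1, integer = TRUE)
  if (is.null(class_balance))
    class_balance <- list(yellowing = rep(1, N_YELLOWING),
                          browning = rep(1, N_BROWNING),
                          drying = rep(1, N_DRYING))
  stopifnot(length(class_balance$yellowing) == N_YELLOWING,
            length(class_balance$browning) == N_BROWNING,
            length(class_balance$drying) == N_DRYING)
  for (nm in names(class_balance)) {
    w <- class_balance[[nm]]
    if (any(w < 0) || sum(w) <= 0)
      abort_field("class_balance",
                  sprintf("%s weights must be non-negative, one positive", nm))
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  withr::with_seed(seed, {
    labs <- sample_state_labels(n, class_balance, correlation)
    img_seeds <- sample.int(2147483646L, n)
    areas <- sample(c("A", "B", "C"), n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
    temp <- round(38 + 30 * labs$progress + rnorm(n, 0, 0.5), 1)
    humid <- round(85 - 55 * labs$progress + rnorm(n, 0, 1), 1)
    stamp <- format(as.POSIXct("2024-08-01 06:00:00", tz = "UTC") +
                      600 * seq_len(n), "%Y-%m-%dT%H:%M:%SZ")
    paths <- file.path(out_dir, sprintf("leaf_%05d.png", seq_len(n)))
    for (i in seq_len(n)) {
      lab <- state_label(labs$yellowing[i], labs$browning[i], labs$drying[i])
      spec <- synthesis_spec(lab, height = height, width = width,
                             background_noise_sd = background_noise_sd,
                             seed = img_seeds[i])
      img <- generate_leaf_image(spec)
      png::writePNG(img$pixels / 255, paths[i])
    }
  })
  manifest <- data.frame(image_path = basename(paths),
                         yellowing = labs$yellowing,
                         browning = labs$browning,
                         drying = labs$drying,
                         area = areas, timestamp = stamp,
                         temperature = temp, humidity = humid)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, fileEncoding = "UTF-8")
  mpath
}

#' Read a dataset manifest
#'
#' @param manifest_path path of a manifest CSV written by
#'   [generate_dataset()] (or following the same schema).
#' @return data.frame with an added `path` column of absolute image paths.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' not found", manifest_path), call. = FALSE)
  m <- read.csv(manifest_path, stringsAsFactors = FALSE,
                fileEncoding = "UTF-8")
  need <- c("image_path", "yellowing", "browning", "drying")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop(sprintf("manifest lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  m$path <- file.path(dirname(manifest_path), m$image_path)
  m
}

#' Load an image file as an 8-bit RGB array
#'
#' Reads a PNG and returns integer 0-255 channels; optionally resizes
#' (bilinear) to a square target size.
#'
#' @param path PNG file path.
#' @param size optional target side length in pixels.
#' @return H x W x 3 numeric array of 0-255 values.
#' @export
load_image <- function(path, size = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (!is.null(size) && (dim(px)[1] != size || dim(px)[2] != size))
    px <- EBImage::resize(px, w = size, h = size)
  round(px * 255)
}
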