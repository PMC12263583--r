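# Independent oracles used to verify the implementation: deliberately slow,
# loop-based, and sharing no code with the package internals.

# Direct evaluation of the 2-D DFT double sum, O(H^2 W^2)
dft2_bruteforce <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0i, h, w)
  for (u in 0:(h - 1)) {
    for (v in 0:(w - 1)) {
      s <- 0i
      for (m in 0:(h - 1)) {
        for (n in 0:(w - 1)) {
          s <- s + gray[m + 1, n + 1] *
            exp(-2i * pi * (u * m / h + v * n / w))
        }
      }
      out[u + 1, v + 1] <- s
    }
  }
  out
}

# Pixel-by-pixel colour histogram with raster first-appearance order
color_histogram_oracle <- function(quantized) {
  h <- dim(quantized)[1]; w <- dim(quantized)[2]
  seen <- character(0)
  counts <- integer(0)
  first <- integer(0)
  rank <- 0L
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      rank <- rank + 1L
      key <- paste(quantized[row, col, ], collapse = ",")
      j <- match(key, seen)
      if (is.na(j)) {
        seen <- c(seen, key)
        counts <- c(counts, 1L)
        first <- c(first, rank)
      } else {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  list(key = seen, count = counts, first = first)
}

# Top-k selection applied to the oracle histogram with the package's
# documented tie-break (frequency desc, first appearance asc, lexicographic)
top_colors_oracle <- function(quantized, k) {
  hobj <- color_histogram_oracle(quantized)
  trip <- do.call(rbind, lapply(strsplit(hobj$key, ","), as.integer))
  code <- trip[, 1] * 1e6 + trip[, 2] * 1e3 + trip[, 3]
  ord <- order(-hobj$count, hobj$first, code)
  take <- ord[seq_len(min(k, length(ord)))]
  list(colors = trip[take, , drop = FALSE],
       frequency = hobj$count[take] / (dim(quantized)[1] * dim(quantized)[2]),
       first_rank = hobj$first[take])
}

# Scalar-loop scaled cosine attention
attention_oracle <- function(q, k, v, tau, b) {
  n <- nrow(q); d <- ncol(q)
  eps <- 1e-8
  s <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      cs <- sum(q[i, ] * k[j, ]) /
        ((sqrt(sum(q[i, ]^2)) + eps) * (sqrt(sum(k[j, ]^2)) + eps))
      s[i, j] <- cs / tau + b[i, j]
    }
  }
  a <- matrix(0, n, n)
  for (i in 1:n) {
    e <- exp(s[i, ] - max(s[i, ]))
    a[i, ] <- e / sum(e)
  }
  list(output = a %*% v, weights = a)
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

tiny_config <- function(drop_path = 0, ...) {
  leafcure_config(input_size = 32, patch = 4, window = 4, embed_dim = 8,
                  depths = c(1, 1), d_spect = 16, d_color = 12,
                  trunk_dim = 24, drop_path = drop_path, ...)
}

demo_image <- function(yellowing = 2, browning = 2, drying = 4, seed = 1,
                       size = 64) {
  generate_leaf_image(synthesis_spec(
    state_label(yellowing, browning, drying),
    height = size, width = size, seed = seed))$pixels
}
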