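test_that("state labels enforce the per-state class ranges", {
  l <- state_label(6, 5, 8)
  expect_s3_class(l, "state_label")
  expect_error(state_label(7, 0, 0), "yellowing")
  expect_error(state_label(0, 6, 0), "browning")
  expect_error(state_label(0, 0, 9), "drying")
  expect_error(state_label(-1, 0, 0), "yellowing")
  expect_error(state_label(1.5, 0, 0), "integer")
})

test_that("browning bins are left-closed/right-open with exact-zero class 0", {
  expect_equal(browning_bin(0), 0L)
  expect_equal(browning_bin(0.05), 1L)
  expect_equal(browning_bin(0.10), 2L)  # boundary goes to the upper bin
  expect_equal(browning_bin(0.1999), 2L)
  expect_equal(browning_bin(0.20), 3L)
  expect_equal(browning_bin(0.30), 4L)
  expect_equal(browning_bin(0.50), 5L)
  expect_equal(browning_bin(0.9), 5L)
})

test_that("synthesis specs validate their fields", {
  lab <- state_label(1, 2, 3)
  expect_error(new_synthesis_spec(lab, height = 16), "height")
  expect_error(new_synthesis_spec(lab, yellow_fraction = 1.4),
               "yellow_fraction")
  # cover outside the labelled browning bin is rejected
  expect_error(new_synthesis_spec(lab, brown_cover = 0.4), "brown_cover")
  s <- synthesis_spec(lab, seed = 3)
  expect_equal(browning_bin(s$brown_cover), lab$browning)
})

test_that("no brown pixels appear when nothing brown is planted", {
  spec <- new_synthesis_spec(state_label(0, 0, 0), brown_cover = 0,
                             yellow_fraction = 0, wrinkle_amplitude = 0,
                             seed = 5)
  img <- generate_leaf_image(spec)
  expect_equal(sum(brown_band_mask(img)), 0)
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
})

test_that("rendering is bit-deterministic in the spec seed", {
  spec <- synthesis_spec(state_label(4, 3, 6), seed = 41)
  expect_identical(generate_leaf_image(spec)$pixels,
                   generate_leaf_image(spec)$pixels)
  spec2 <- synthesis_spec(state_label(4, 3, 6), seed = 42)
  expect_false(identical(generate_leaf_image(spec2)$pixels,
                         generate_leaf_image(spec)$pixels))
})

test_that("planted brown cover is recovered within 0.02 and in its bin", {
  for (b in 0:5) {
    for (s in 1:2) {
      spec <- synthesis_spec(state_label(sample(0:6, 1), b,
                                         sample(0:8, 1)),
                             seed = 600 + 10 * b + s)
      img <- generate_leaf_image(spec)
      fr <- mean(brown_band_mask(img))
      expect_lt(abs(fr - spec$brown_cover), 0.02)
      expect_equal(browning_bin(fr), b)
    }
  }
})

test_that("mean hue moves monotonically from green toward yellow", {
  hues <- vapply(seq(0, 1, length.out = 8), function(yf) {
    img <- generate_leaf_image(new_synthesis_spec(
      state_label(0, 0, 0), yellow_fraction = yf, seed = 5))
    m <- apply(img$pixels, 3, mean)
    grDevices::rgb2hsv(m[1], m[2], m[3], maxColorValue = 255)[1]
  }, numeric(1))
  expect_true(all(diff(hues) < 0))  # hue angle falls from green to yellow
})

test_that("high-frequency energy strictly increases with wrinkle amplitude", {
  highs <- vapply(seq(0, 20, length.out = 7), function(a) {
    img <- generate_leaf_image(new_synthesis_spec(
      state_label(0, 0, 0), wrinkle_amplitude = a, seed = 11))
    frequency_intensity(dft2(to_grayscale(img$pixels)))$high
  }, numeric(1))
  expect_true(all(diff(highs) > 0))
})

test_that("the planted drying signal is recoverable by a threshold rule", {
  vals <- numeric(0); labs <- integer(0)
  withr::with_seed(1, {
    for (d in 0:8) {
      for (i in 1:5) {
        img <- generate_leaf_image(synthesis_spec(
          state_label(sample(0:6, 1), sample(0:3, 1), d),
          seed = 7000 + d * 97 + i))
        vals <- c(vals, frequency_intensity(dft2(
          to_grayscale(img$pixels)))$high)
        labs <- c(labs, d)
      }
    }
  })
  mns <- tapply(vals, labs, mean)
  pred <- vapply(vals, function(v)
    as.integer(names(mns)[which.min(abs(mns - v))]), integer(1))
  expect_gte(mean(pred == labs), 0.7)
})

test_that("datasets round-trip through PNG and manifest bit-exactly", {
  dir <- tempfile("roundtrip")
  mp <- generate_dataset(10, seed = 7, out_dir = dir)
  man <- read_manifest(mp)
  expect_equal(nrow(man), 10)
  expect_true(all(man$yellowing %in% 0:6))
  expect_true(all(man$browning %in% 0:5))
  expect_true(all(man$drying %in% 0:8))
  expect_true(all(c("area", "timestamp", "temperature", "humidity") %in%
                    names(man)))
  # regenerate the same dataset: identical labels and identical pixels
  dir2 <- tempfile("roundtrip2")
  mp2 <- generate_dataset(10, seed = 7, out_dir = dir2)
  man2 <- read_manifest(mp2)
  expect_equal(man$yellowing, man2$yellowing)
  for (i in c(1, 5, 10)) {
    expect_identical(png::readPNG(man$path[i]), png::readPNG(man2$path[i]))
  }
  # a written image read back equals the in-memory rendering
  withr::with_seed(7, {
    labs <- leafcure:::sample_state_labels(
      10, list(yellowing = rep(1, 7), browning = rep(1, 6),
               drying = rep(1, 9)),
      c(yd = 0.8, yb = 0.35, bd = 0.35))
    img_seeds <- sample.int(2147483646L, 10)
  })
  img1 <- generate_leaf_image(synthesis_spec(
    state_label(labs$yellowing[1], labs$browning[1], labs$drying[1]),
    seed = img_seeds[1]))
  expect_equal(round(png::readPNG(man$path[1]) * 255),
               img1$pixels, ignore_attr = TRUE)
})

test_that("different seeds give different pixels but one schema", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- read_manifest(generate_dataset(6, seed = 1, out_dir = d1))
  m2 <- read_manifest(generate_dataset(6, seed = 2, out_dir = d2))
  expect_identical(names(m1), names(m2))
  expect_false(identical(png::readPNG(m1$path[1]),
                         png::readPNG(m2$path[1])))
})

test_that("marginal class frequencies follow the requested weights", {
  withr::with_seed(123, {
    labs <- leafcure:::sample_state_labels(
      900, list(yellowing = rep(1, 7), browning = rep(1, 6),
                drying = rep(1, 9)),
      c(yd = 0.8, yb = 0.35, bd = 0.35))
  })
  for (s in c("yellowing", "browning", "drying")) {
    k <- c(yellowing = 7, browning = 6, drying = 9)[[s]]
    counts <- tabulate(labs[[s]] + 1L, nbins = k)
    p <- stats::chisq.test(counts, p = rep(1 / k, k))$p.value
    expect_gt(p, 0.01)
    # empirical frequencies within 3 binomial sd of the target
    expect_true(all(abs(counts / 900 - 1 / k) <=
                      3 * sqrt((1 / k) * (1 - 1 / k) / 900)))
  }
  # positive association between yellowing and drying
  expect_gt(cor(labs$yellowing, labs$drying, method = "spearman"), 0.5)
})

test_that("an unwritable output directory raises an I/O error", {
  expect_error(generate_dataset(2, out_dir = "/proc/nonexistent/x"),
               "cannot create")
})

test_that("class balance weights are validated", {
  expect_error(generate_dataset(
    5, class_balance = list(yellowing = rep(-1, 7), browning = rep(1, 6),
                            drying = rep(1, 9))),
    "non-negative")
  expect_error(generate_dataset(0), "n")
})
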