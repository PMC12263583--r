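test_that("center crop keeps the documented window", {
  img <- random_rgb_image(100, 100)
  expect_identical(center_crop(img, 1), img)
  cr <- center_crop(img, 0.5)
  expect_equal(dim(cr), c(50, 50, 3))
  expect_identical(cr, img[26:75, 26:75, , drop = FALSE])
  expect_error(center_crop(img, 0), "\\(0, 1]")
  expect_error(center_crop(img, 1.2), "\\(0, 1]")
})

test_that("cropping removes a noise-only border from the histogram", {
  img <- array(0, dim = c(40, 40, 3))
  img[, , 1] <- 200  # signal colour fills everything
  img[c(1:10, 31:40), , 2] <- 255  # noise colour only in the border rows
  img[, c(1:10, 31:40), 2] <- 255
  cr <- center_crop(img, 0.5)
  q <- quantize_colors(cr, 4)
  d <- common_color_descriptor(q, 5)
  expect_equal(sum(d$pad_mask), 1L)
  expect_equal(d$frequency[1], 1)
})

test_that("uniform quantization bins channels as floor(v q / 256)", {
  img <- random_rgb_image(32, 32)
  q4 <- quantize_colors(img, 4)
  expect_true(all(q4 %in% 0:3))
  codes <- unique(as.vector(q4[, , 1] * 16 + q4[, , 2] * 4 + q4[, , 3]))
  expect_lte(length(codes), 64)
  q256 <- quantize_colors(img, 256)
  expect_equal(as.vector(q256), as.vector(img))
  expect_error(quantize_colors(img, 1), "q_levels")
})

test_that("q_levels = 2 counts the occupied colour octants", {
  withr::with_seed(21, {
    img <- random_rgb_image(64, 64)
    q <- quantize_colors(img, 2)
    occupied <- unique(paste(
      as.vector(img[, , 1] >= 128), as.vector(img[, , 2] >= 128),
      as.vector(img[, , 3] >= 128)))
    d <- common_color_descriptor(q, 8)
    expect_equal(sum(d$pad_mask), length(occupied))
  })
})

test_that("descriptor handles degenerate and two-colour images", {
  mono <- array(0, dim = c(8, 8, 3)); mono[, , 2] <- 100
  d <- common_color_descriptor(quantize_colors(mono, 4), 6)
  expect_equal(sum(d$pad_mask), 1L)
  expect_equal(d$frequency, c(1, rep(0, 5)))
  expect_equal(d$first_rank[1], 1)
  # 75% black / 25% red split
  img <- array(0, dim = c(8, 8, 3))
  img[1:2, , 1] <- 255  # 16 of 64 pixels red, rest black
  d2 <- common_color_descriptor(quantize_colors(img, 4), 2)
  expect_equal(d2$frequency, c(0.75, 0.25))
  expect_equal(d2$colors[1, ], c(r = 0, g = 0, b = 0))
  expect_equal(d2$colors[2, ], c(r = 3, g = 0, b = 0))
})

test_that("frequency ties break by first appearance then colour triple", {
  img <- array(0, dim = c(2, 4, 3))
  # raster order row 1: A B A B ; row 2: B A B A -> A first at 1, both 50%
  img[1, c(2, 4), 1] <- 255
  img[2, c(1, 3), 1] <- 255
  d <- common_color_descriptor(quantize_colors(img, 4), 2)
  expect_equal(d$colors[1, ], c(r = 0, g = 0, b = 0))
  expect_equal(d$first_rank, c(1, 2))
  d_again <- common_color_descriptor(quantize_colors(img, 4), 2)
  expect_identical(d, d_again)
})

test_that("descriptor matches the pixel-enumeration oracle on random images", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      img <- random_rgb_image(sample(6:12, 1), sample(6:12, 1))
      q <- quantize_colors(img, sample(c(2, 4, 8), 1))
      k <- sample(3:8, 1)
      d <- common_color_descriptor(q, k)
      o <- top_colors_oracle(q, k)
      kr <- sum(d$pad_mask)
      expect_equal(kr, nrow(o$colors))
      expect_equal(unname(d$colors[seq_len(kr), , drop = FALSE]),
                   unname(o$colors))
      expect_equal(d$frequency[seq_len(kr)], o$frequency)
      expect_equal(d$first_rank[seq_len(kr)], o$first_rank)
    }
  })
})

test_that("descriptor is invariant to count/order-preserving pixel moves", {
  withr::with_seed(5, {
    img <- random_rgb_image(10, 10)
    q <- quantize_colors(img, 2)
    d <- common_color_descriptor(q, 6)
    # swapping two pixels of identical colour, or permuting pixels after
    # every colour's first appearance while keeping counts, changes nothing
    q2 <- q
    codes <- t(q[, , 1] * 4 + q[, , 2] * 2 + q[, , 3])  # raster order
    pos <- which(as.vector(codes) == as.vector(codes)[1])
    if (length(pos) >= 3) {
      # identical-colour swap is a no-op on the array itself
      expect_identical(common_color_descriptor(q2, 6), d)
    }
    # reversing the final raster row leaves counts intact; first ranks of
    # retained colours are unchanged when all first appearances are earlier
    lastrow <- dim(q)[1]
    firsts <- d$first_rank[d$pad_mask]
    if (all(firsts <= (lastrow - 1) * dim(q)[2])) {
      q3 <- q
      q3[lastrow, , ] <- q[lastrow, rev(seq_len(dim(q)[2])), ]
      expect_equal(common_color_descriptor(q3, 6), d)
    }
  })
})

test_that("increasing k keeps previously retained colours (prefix property)", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      img <- random_rgb_image(12, 12)
      q <- quantize_colors(img, 4)
      d5 <- common_color_descriptor(q, 5)
      d9 <- common_color_descriptor(q, 9)
      k5 <- sum(d5$pad_mask)
      expect_equal(d9$colors[seq_len(k5), ], d5$colors[seq_len(k5), ])
    }
  })
})

test_that("a dominant planted colour is always entry 0", {
  for (s in 1:5) {
    img <- demo_image(browning = 0, seed = 300 + s)
    crop <- center_crop(img, 0.6)
    q <- quantize_colors(crop, 4)
    d <- common_color_descriptor(q, 20)
    expect_gte(d$frequency[1], 0.4)
    # leaf body colour: low blue channel bin
    expect_equal(unname(d$colors[1, "b"]), 0)
  }
})

test_that("retained-colour mask concentrates on the leaf", {
  img <- demo_image(seed = 17)
  crop <- center_crop(img, 0.6)
  q <- quantize_colors(crop, 4)
  d <- common_color_descriptor(q, 6)
  m <- retained_color_mask(q, d)
  expect_equal(dim(m), dim(crop)[1:2])
  expect_gt(mean(m), 0.8)  # the crop is dominated by leaf pixels
})

test_that("descriptor serialization and JSON export are stable", {
  img <- demo_image(seed = 23)
  d <- common_color_descriptor(quantize_colors(center_crop(img, 0.6), 4), 20)
  v <- descriptor_vector(d)
  expect_length(v, 100)
  expect_true(all(v >= 0 & v <= 1))
  path <- tempfile(fileext = ".json")
  write_descriptor_json(d, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$q_levels, 4)
  expect_equal(nrow(back$colors), sum(d$pad_mask))
})

test_that("colour feature layer is a single FC with checkable gradients", {
  cfg <- tiny_config()
  model <- leafcure_model(cfg, seed = 4)
  img <- demo_image(seed = 3)
  d <- common_color_descriptor(quantize_colors(center_crop(img, 0.6),
                                               cfg$q_levels), cfg$k_colors)
  f1 <- color_feature_extractor(d, model)
  f2 <- color_feature_extractor(d, model)
  expect_identical(f1, f2)
  expect_length(f1, cfg$d_color)
  # zero weights -> zero output on an all-padded descriptor
  m0 <- model
  m0$params[["ccfm.w"]] <- m0$params[["ccfm.w"]] * 0
  empty <- d
  empty$pad_mask[] <- FALSE
  expect_equal(color_feature_extractor(empty, m0), numeric(cfg$d_color))
  # finite-difference gradient check
  v <- descriptor_vector(d)
  p <- model$params
  fwd <- leafcure:::ccfm_fwd(v, p)
  acc <- new.env(parent = emptyenv()); acc$g <- list()
  leafcure:::ccfm_bwd(rep(1, cfg$d_color), fwd, p, acc)
  eps <- 1e-5
  withr::with_seed(2, {
    for (i in sample(length(p[["ccfm.w"]]), 5)) {
      p2 <- p; p2[["ccfm.w"]][i] <- p[["ccfm.w"]][i] + eps
      lp <- sum(leafcure:::ccfm_fwd(v, p2)$f)
      p2[["ccfm.w"]][i] <- p[["ccfm.w"]][i] - eps
      lm <- sum(leafcure:::ccfm_fwd(v, p2)$f)
      expect_equal(acc$g[["ccfm.w"]][i], (lp - lm) / (2 * eps),
                   tolerance = 1e-4)
    }
  })
})
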