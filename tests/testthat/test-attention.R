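test_that("QKV projection is one joint linear map split evenly", {
  f0 <- matrix(0, 3, 4)
  w <- matrix(rnorm(4 * 12), 4, 12)
  p0 <- project_qkv(f0, w)
  expect_equal(p0$q, matrix(0, 3, 4))
  expect_equal(p0$k, matrix(0, 3, 4))
  expect_equal(p0$v, matrix(0, 3, 4))
  wid <- cbind(diag(4), diag(4), diag(4))
  f <- matrix(rnorm(12), 3, 4)
  pid <- project_qkv(f, wid)
  expect_equal(pid$q, f)
  expect_equal(pid$k, f)
  expect_equal(pid$v, f)
  withr::with_seed(31, {
    f <- matrix(rnorm(12), 3, 4)
    w <- matrix(rnorm(4 * 9), 4, 9)
    pr <- project_qkv(f, w)
    qkv <- matrix(0, 3, 9)
    for (i in 1:3) for (j in 1:9) qkv[i, j] <- sum(f[i, ] * w[, j])
    expect_equal(pr$q, qkv[, 1:3], tolerance = 1e-12)
    expect_equal(pr$k, qkv[, 4:6], tolerance = 1e-12)
    expect_equal(pr$v, qkv[, 7:9], tolerance = 1e-12)
  })
  expect_error(project_qkv(matrix(0, 3, 4), matrix(0, 5, 12)), "mismatch")
})

test_that("single-token attention returns V exactly", {
  q <- matrix(rnorm(3), 1, 3)
  k <- matrix(rnorm(3), 1, 3)
  v <- matrix(c(2, -1, 5), 1, 3)
  out <- scaled_cosine_attention(q, k, v, tau = 0.7)
  expect_equal(out$output, v)
  expect_equal(out$weights, matrix(1, 1, 1))
})

test_that("attention weights are invariant to positive row rescaling of Q", {
  withr::with_seed(12, {
    q <- matrix(rnorm(8), 4, 2)
    k <- matrix(rnorm(8), 4, 2)
    v <- matrix(rnorm(8), 4, 2)
    b <- matrix(rnorm(16) * 0.2, 4, 4)
    a1 <- scaled_cosine_attention(q, k, v, tau = 0.5, b = b)
    # invariance is exact up to the epsilon guard on the norms
    scales <- c(0.1, 3, 17, 0.04)
    a2 <- scaled_cosine_attention(q * scales, k, v, tau = 0.5, b = b)
    expect_equal(a1$weights, a2$weights, tolerance = 1e-6)
  })
})

test_that("attention matches the scalar-loop oracle on small instances", {
  withr::with_seed(44, {
    for (rep in 1:8) {
      n <- sample(2:4, 1); d <- sample(2:4, 1)
      q <- matrix(rnorm(n * d), n, d)
      k <- matrix(rnorm(n * d), n, d)
      v <- matrix(rnorm(n * d), n, d)
      b <- matrix(rnorm(n * n) * 0.3, n, n)
      tau <- runif(1, 0.2, 2)
      got <- scaled_cosine_attention(q, k, v, tau, b)
      want <- attention_oracle(q, k, v, tau, b)
      expect_equal(got$output, want$output, tolerance = 1e-9)
      expect_equal(got$weights, want$weights, tolerance = 1e-9)
    }
  })
})

test_that("attention rows always sum to one, even with zero-norm tokens", {
  withr::with_seed(90, {
    for (rep in 1:100) {
      n <- sample(2:6, 1); d <- sample(2:5, 1)
      q <- matrix(rnorm(n * d), n, d)
      if (rep %% 7 == 0) q[1, ] <- 0
      k <- matrix(rnorm(n * d), n, d)
      if (rep %% 11 == 0) k[n, ] <- 0
      v <- matrix(rnorm(n * d), n, d)
      b <- matrix(rnorm(n * n), n, n)
      tau <- runif(1, 0.05, 3)
      a <- scaled_cosine_attention(q, k, v, tau, b)
      expect_true(all(is.finite(a$output)))
      expect_equal(rowSums(a$weights), rep(1, n), tolerance = 1e-6)
    }
  })
})

test_that("compiled window attention equals the reference R path", {
  withr::with_seed(3, {
    f <- array(rnorm(16 * 8 * 3), c(16, 8, 3))
    w <- matrix(rnorm(8 * 24) * 0.3, 8, 24)
    b <- matrix(rnorm(256) * 0.1, 16, 16)
    inv_tau <- 1.3
    got <- leafcure:::cpp_win_attn_fwd(f, w, inv_tau, b)
    for (s in 1:3) {
      pr <- project_qkv(f[, , s], w)
      ref <- scaled_cosine_attention(pr$q, pr$k, pr$v, tau = 1 / inv_tau,
                                     b = b)
      expect_equal(got$O[, , s], ref$output, tolerance = 1e-12)
      expect_equal(got$A[, , s], ref$weights, tolerance = 1e-12)
    }
  })
})

test_that("relative position bias gives equal offsets equal bias", {
  params <- init_bias_net(8)
  b1 <- relative_position_bias(1, params)
  expect_equal(dim(b1), c(1, 1))
  b2 <- relative_position_bias(2, params)
  # tokens 1 and 2 sit one step apart horizontally, as do tokens 3 and 4
  expect_equal(b2[1, 2], b2[3, 4])
  expect_equal(b2[2, 1], b2[4, 3])
  # direct enumeration oracle over all 16 pairs of the 2 x 2 window
  pos <- expand.grid(x = 1:2, y = 1:2)
  g <- function(dy, dx) {
    z <- c(sign(dy) * log(1 + abs(dy)) / log(2),
           sign(dx) * log(1 + abs(dx)) / log(2))
    h <- pmax(z %*% params$w1 + params$b1, 0)
    as.numeric(h %*% params$w2 + params$b2)
  }
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(b2[i, j], g(pos$y[i] - pos$y[j], pos$x[i] - pos$x[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("sign-symmetric offsets get symmetric bias under an even network", {
  params <- init_bias_net(6)
  # force evenness: first-layer weights zero => constant output
  params$w1[] <- 0
  b <- relative_position_bias(3, params)
  expect_equal(max(b) - min(b), 0)
})

test_that("patch merging quarters tokens and doubles width", {
  d <- 6
  w <- matrix(rnorm(4 * d * 2 * d), 4 * d, 2 * d)
  b <- rnorm(2 * d)
  tok <- matrix(rnorm(64 * d), 64, d)
  m1 <- patch_split_merge(tok, 8, w, b)
  expect_equal(dim(m1), c(16, 2 * d))
  w2 <- matrix(rnorm(8 * d * 4 * d), 8 * d, 4 * d)
  m2 <- patch_split_merge(m1, 4, w2, rnorm(4 * d))
  expect_equal(dim(m2), c(4, 4 * d))
  # constant tokens stay constant under a linear merge
  tokc <- matrix(rep(seq_len(d), each = 64), 64, d)
  mc <- patch_split_merge(tokc, 8, w, b)
  expect_equal(mc, matrix(rep(mc[1, ], each = 16), 16, 2 * d))
  expect_equal(mc[1, ], as.vector(rep(seq_len(d), 4) %*% w) + b)
  expect_error(patch_split_merge(tok[1:9, ], 3, w, b), "divisible")
})

test_that("patch splitting validates divisibility and centres pixels", {
  img <- demo_image(seed = 2, size = 64)
  tok <- patch_split(img, 4)
  expect_equal(dim(tok), c(256, 48))
  expect_true(all(tok >= -0.5 & tok <= 0.5))
  odd <- array(0, dim = c(30, 30, 3))
  expect_error(patch_split(odd, 4), "pad")
})

test_that("fusion head returns three normalized distributions", {
  cfg <- tiny_config()
  model <- leafcure_model(cfg, seed = 8)
  # zero features with zero weights -> uniform distributions
  m0 <- model
  for (nm in grep("^(trunk|head)", names(m0$params), value = TRUE))
    m0$params[[nm]] <- m0$params[[nm]] * 0
  dims <- c(leafcure:::backbone_out_dim(cfg), cfg$d_spect, cfg$d_color)
  pred0 <- fuse_and_classify(numeric(dims[1]), numeric(dims[2]),
                             numeric(dims[3]), m0)
  expect_equal(pred0$p_yellow, rep(1 / 7, 7))
  expect_equal(pred0$p_brown, rep(1 / 6, 6))
  expect_equal(pred0$p_dry, rep(1 / 9, 9))
  withr::with_seed(10, {
    f1 <- rnorm(dims[1]); f2 <- rnorm(dims[2]); f3 <- rnorm(dims[3])
  })
  pr <- fuse_and_classify(f1, f2, f3, model)
  expect_equal(sum(pr$p_yellow), 1, tolerance = 1e-6)
  expect_equal(sum(pr$p_brown), 1, tolerance = 1e-6)
  expect_equal(sum(pr$p_dry), 1, tolerance = 1e-6)
  expect_identical(pr, fuse_and_classify(f1, f2, f3, model))
  bad <- f1; bad[1] <- NaN
  expect_error(fuse_and_classify(bad, f2, f3, model), "f_img")
})

test_that("multi-state loss has the cross-entropy closed forms", {
  lab <- state_label(3, 1, 6)
  perfect <- structure(list(p_yellow = leafcure:::onehot(3, 7),
                            p_brown = leafcure:::onehot(1, 6),
                            p_dry = leafcure:::onehot(6, 9)),
                       class = "state_prediction")
  expect_equal(multi_state_loss(perfect, lab), 0, tolerance = 1e-9)
  uniform <- structure(list(p_yellow = rep(1 / 7, 7),
                            p_brown = rep(1 / 6, 6),
                            p_dry = rep(1 / 9, 9)),
                       class = "state_prediction")
  expect_equal(multi_state_loss(uniform, lab), log(7) + log(6) + log(9),
               tolerance = 1e-9)
  withr::with_seed(19, {
    for (rep in 1:20) {
      p <- structure(list(
        p_yellow = as.vector(leafcure:::softmax_rows(rnorm(7))),
        p_brown = as.vector(leafcure:::softmax_rows(rnorm(6))),
        p_dry = as.vector(leafcure:::softmax_rows(rnorm(9)))),
        class = "state_prediction")
      expect_gte(multi_state_loss(p, lab), 0)
    }
  })
  expect_error(state_label(7, 0, 0), "yellowing")
})
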