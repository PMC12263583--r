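# Layer primitives with explicit forward/backward passes. Parameters live in
# a flat named list of numeric arrays; every backward returns gradients of
# the same shapes. Window attention and the im2col convolutions call the
# compiled Armadillo kernels.

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(rnorm(nr * nc, 0, sd), nr, nc)
}

linear_fwd <- function(x, w, b) {
  sweep(x %*% w, 2L, b, `+`)
}

linear_bwd <- function(x, w, dy) {
  list(dx = dy %*% t(w), dw = t(x) %*% dy, db = colSums(dy))
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`),
       xhat = xhat, inv = inv, xc = xc)
}

layernorm_bwd <- function(cache, g, dy) {
  d <- ncol(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  # dx = inv/d * (d*dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$inv / d) * (d * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dg = dg, db = db)
}

# ---------------------------------------------------------------------------
# Exported reference operations (pure R). The training path uses the fused
# compiled kernels; equality of the two routes is asserted in the tests.

#' Project token features to queries, keys and values
#'
#' One joint linear map `W` of shape d' x 3d applied to the N x d' token
#' feature matrix, split evenly into Q, K, V (each N x d).
#'
#' @param f N x d' token feature matrix.
#' @param w d' x 3d projection weight matrix (3d a multiple of 3).
#' @return list with N x d matrices `q`, `k`, `v`.
#' @export
project_qkv <- function(f, w) {
  if (!is.matrix(f) || !is.matrix(w) || nrow(w) != ncol(f))
    stop("dimension mismatch: need ncol(f) == nrow(w)", call. = FALSE)
  if (ncol(w) %% 3L != 0L)
    stop("ncol(w) must be a multiple of 3", call. = FALSE)
  d <- ncol(w) %/% 3L
  qkv <- f %*% w
  list(q = qkv[, 1:d, drop = FALSE],
       k = qkv[, (d + 1):(2 * d), drop = FALSE],
       v = qkv[, (2 * d + 1):(3 * d), drop = FALSE])
}

cosine_rows <- function(q, k, eps = 1e-8) {
  qn <- q / (sqrt(rowSums(q^2)) + eps)
  kn <- k / (sqrt(rowSums(k^2)) + eps)
  qn %*% t(kn)
}

#' Scaled cosine attention
#'
#' Attention(Q, K, V) = SoftMax(cos(Q, K) / tau + B) V, where cos(Q, K) is
#' the N x N matrix of pairwise cosine similarities between query and key
#' rows, tau a positive learnable temperature and B a relative position
#' bias. Cosines are epsilon-guarded (1e-8 on the norms) so zero rows never
#' produce NaN. Attention weight rows sum to one; the weights are invariant
#' to positive per-row rescaling of Q or K.
#'
#' @param q,k,v N x d matrices.
#' @param tau positive scalar temperature.
#' @param b N x N bias matrix (default zero).
#' @return list with `output` (N x d) and `weights` (N x N, rows sum to 1).
#' @export
scaled_cosine_attention <- function(q, k, v, tau, b = NULL) {
  check_number(tau, "tau")
  if (tau <= 0) abort_field("tau", "must be positive")
  n <- nrow(q)
  if (is.null(b)) b <- matrix(0, n, n)
  if (!all(dim(b) == c(n, n)))
    stop("`b` must be N x N", call. = FALSE)
  s <- cosine_rows(q, k) / tau + b
  a <- softmax_rows(s)
  list(output = a %*% v, weights = a)
}

#' Continuous relative position bias over a window grid
#'
#' Every ordered pair of patches (i, j) in a `win x win` window has an
#' offset (dy, dx) = position(i) - position(j). The offset is log-spaced
#' (`sign(d) * log(1 + |d|) / log(1 + win - 1)`) and fed to a small
#' two-layer fully connected network g, giving the N x N bias matrix used by
#' [scaled_cosine_attention()]. Equal offsets receive equal bias.
#'
#' @param win window side length in patches.
#' @param params list with `w1` (2 x hidden), `b1`, `w2` (hidden x 1), `b2`;
#'   see [init_bias_net()].
#' @return N x N bias matrix, N = win^2.
#' @export
relative_position_bias <- function(win, params) {
  check_number(win, "win", 1, integer = TRUE)
  tab <- bias_tables(win)
  vals <- bias_net_fwd(tab$offsets, params)$out
  matrix(vals[tab$index], win * win, win * win)
}

#' Initialize the relative position bias network
#'
#' @param hidden hidden width of the two-layer bias network.
#' @param sd init scale.
#' @return parameter list for [relative_position_bias()].
#' @export
init_bias_net <- function(hidden = 16L, sd = 0.02) {
  list(w1 = init_mat(2L, hidden, sd), b1 = numeric(hidden),
       w2 = init_mat(hidden, 1L, sd), b2 = numeric(1L))
}

# Distinct offsets of a win x win grid (log-spaced, normalized) and the
# N x N index table into them. Tokens are in row-major raster order.
bias_tables <- function(win) {
  pos <- expand.grid(x = seq_len(win), y = seq_len(win))  # row-major: x fast
  n <- win * win
  dy <- outer(pos$y, pos$y, `-`)
  dx <- outer(pos$x, pos$x, `-`)
  id <- (dy + win - 1L) * (2L * win - 1L) + (dx + win - 1L) + 1L
  m <- 2L * win - 1L
  offs <- expand.grid(dx = -(win - 1L):(win - 1L),
                      dy = -(win - 1L):(win - 1L))
  logd <- function(d) {
    if (win == 1L) return(d * 0)
    sign(d) * log(1 + abs(d)) / log(win)
  }
  list(offsets = cbind(logd(offs$dy), logd(offs$dx)),
       index = matrix(id, n, n), n_off = m * m)
}

bias_net_fwd <- function(x, params) {
  h_pre <- linear_fwd(x, params$w1, params$b1)
  h <- relu(h_pre)
  out <- linear_fwd(h, params$w2, params$b2)
  list(out = as.vector(out), h = h, h_pre = h_pre, x = x)
}

bias_net_bwd <- function(cache, params, dout) {
  g2 <- linear_bwd(cache$h, params$w2, matrix(dout, ncol = 1L))
  dh <- g2$dx * (cache$h_pre > 0)
  g1 <- linear_bwd(cache$x, params$w1, dh)
  list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db)
}

# ---------------------------------------------------------------------------
# Token grid helpers. Tokens are stored as an N x d matrix in row-major
# raster order over a g x g grid: token t = (y - 1) * g + x.

#' Split an image into non-overlapping patch tokens
#'
#' Each `patch x patch` block of the (0-255) image becomes one token whose
#' raw feature vector is the flattened, 0-1 scaled, 0.5-centred pixel block.
#'
#' @param image H x W x 3 array with H = W divisible by `patch`.
#' @param patch patch side length in pixels.
#' @return (H/patch * W/patch) x (3 * patch^2) matrix of token features in
#'   row-major grid order.
#' @export
patch_split <- function(image, patch) {
  check_rgb_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h %% patch != 0L || w %% patch != 0L)
    stop(sprintf(
      "image side (%d x %d) not divisible by patch %d; pad to %d x %d",
      h, w, patch, patch * ceiling(h / patch), patch * ceiling(w / patch)),
      call. = FALSE)
  gy <- h %/% patch; gx <- w %/% patch
  x <- image / 255 - 0.5
  out <- matrix(0, gy * gx, 3L * patch * patch)
  t <- 0L
  for (iy in seq_len(gy)) {
    rows <- ((iy - 1L) * patch + 1L):(iy * patch)
    for (ix in seq_len(gx)) {
      t <- t + 1L
      cols <- ((ix - 1L) * patch + 1L):(ix * patch)
      out[t, ] <- as.vector(x[rows, cols, ])
    }
  }
  out
}

# 4-column index matrix: merged token t' gathers old tokens in fixed
# (top-left, top-right, bottom-left, bottom-right) order
merge_index <- function(g) {
  if (g %% 2L != 0L)
    stop(sprintf("grid side %d not divisible by 2; pad the token grid", g),
         call. = FALSE)
  h <- g %/% 2L
  idx <- matrix(0L, h * h, 4L)
  t <- 0L
  for (y in seq_len(h)) {
    for (x in seq_len(h)) {
      t <- t + 1L
      oy <- 2L * y - 1L; ox <- 2L * x - 1L
      idx[t, ] <- c((oy - 1L) * g + ox, (oy - 1L) * g + ox + 1L,
                    oy * g + ox, oy * g + ox + 1L)
    }
  }
  idx
}

#' Merge 2 x 2 neighbouring patch tokens
#'
#' Hierarchical token reduction: each 2 x 2 block of grid neighbours is
#' concatenated (4d features) and linearly projected, quartering the token
#' count while (with the default projection width 2d) doubling the channel
#' width.
#'
#' @param tokens N x d token matrix over a g x g grid (N = g^2, g even).
#' @param g grid side length.
#' @param w 4d x d_out projection matrix.
#' @param b length-d_out bias.
#' @return (g/2)^2 x d_out merged token matrix.
#' @export
patch_split_merge <- function(tokens, g, w, b) {
  if (nrow(tokens) != g * g)
    stop("nrow(tokens) must equal g^2", call. = FALSE)
  idx <- merge_index(g)
  xc <- cbind(tokens[idx[, 1], , drop = FALSE], tokens[idx[, 2], , drop = FALSE],
              tokens[idx[, 3], , drop = FALSE], tokens[idx[, 4], , drop = FALSE])
  linear_fwd(xc, w, b)
}

merge_bwd <- function(tokens, g, w, dy) {
  idx <- merge_index(g)
  d <- ncol(tokens)
  xc <- cbind(tokens[idx[, 1], , drop = FALSE], tokens[idx[, 2], , drop = FALSE],
              tokens[idx[, 3], , drop = FALSE], tokens[idx[, 4], , drop = FALSE])
  g1 <- linear_bwd(xc, w, dy)
  dtok <- matrix(0, nrow(tokens), d)
  for (kk in 1:4) {
    cols <- ((kk - 1L) * d + 1L):(kk * d)
    dtok[idx[, kk], ] <- dtok[idx[, kk], ] + g1$dx[, cols, drop = FALSE]
  }
  list(dtokens = dtok, dw = g1$dw, db = g1$db)
}

# Window partition index: column k lists the token indices (row-major within
# the window) of window k on a g x g grid with window side `win`.
window_index <- function(g, win) {
  if (g %% win != 0L)
    stop(sprintf("grid side %d not divisible by window %d", g, win),
         call. = FALSE)
  gw <- g %/% win
  idx <- matrix(0L, win * win, gw * gw)
  k <- 0L
  for (wy in seq_len(gw)) {
    for (wx in seq_len(gw)) {
      k <- k + 1L
      t <- 0L
      for (y in seq_len(win)) {
        for (x in seq_len(win)) {
          t <- t + 1L
          gy <- (wy - 1L) * win + y
          gx <- (wx - 1L) * win + x
          idx[t, k] <- (gy - 1L) * g + gx
        }
      }
    }
  }
  idx
}

# ---------------------------------------------------------------------------
# AdamW optimizer over a flat named list of arrays (decoupled weight decay,
# global-norm gradient clipping applied by the caller).

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01, no_decay = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    wd <- if (!is.null(no_decay) && nm %in% no_decay) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}
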