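#' Model configuration
#'
#' Architecture and preprocessing settings of the three-branch recognizer.
#' The reference backbone is a deliberately small two-stage windowed
#' scaled-cosine-attention transformer so that CPU training is practical;
#' a pretrained extractor of any size can be plugged in through `backbone`.
#'
#' @param input_size square input side in pixels (divisible by
#'   `patch * 2^(stages-1) * window`).
#' @param patch patch side in pixels.
#' @param window window side in patches.
#' @param embed_dim token width of the first stage (doubles per stage).
#' @param depths integer vector, attention blocks per stage.
#' @param mlp_ratio hidden width multiplier of the per-block MLP.
#' @param bias_hidden hidden width of the relative-position bias network.
#' @param d_spect dimension of the spectral feature F_spect.
#' @param d_color dimension of the colour feature F_color.
#' @param q_levels colour quantization levels per channel (tuned value 4).
#' @param k_colors retained common colours (tuned value 20).
#' @param crop_fraction centre-crop fraction for the colour branch.
#' @param cutoff_fraction radial cutoff of the high-frequency band.
#' @param trunk_dim width of the shared fully connected trunk.
#' @param drop_path stochastic-depth rate on backbone blocks.
#' @param use_backbone,use_ffm,use_ccfm branch switches (for ablations).
#' @param backbone `"tiny"` for the reference backbone, or a function
#'   `image -> numeric vector` acting as a pretrained feature adapter.
#' @param adapter_dim F_img dimension when `backbone` is a function.
#' @return list of class `leafcure_config`.
#' @export
leafcure_config <- function(input_size = 64L, patch = 4L, window = 4L,
                            embed_dim = 32L, depths = c(1L, 1L),
                            mlp_ratio = 2, bias_hidden = 16L,
                            d_spect = 128L, d_color = 64L,
                            q_levels = 4L, k_colors = 20L,
                            crop_fraction = 0.6, cutoff_fraction = 0.25,
                            trunk_dim = 256L, drop_path = 0.1,
                            use_backbone = TRUE, use_ffm = TRUE,
                            use_ccfm = TRUE, backbone = "tiny",
                            adapter_dim = NULL) {
  cfg <- list(input_size = as.integer(input_size), patch = as.integer(patch),
              window = as.integer(window), embed_dim = as.integer(embed_dim),
              depths = as.integer(depths), mlp_ratio = mlp_ratio,
              bias_hidden = as.integer(bias_hidden),
              d_spect = as.integer(d_spect), d_color = as.integer(d_color),
              q_levels = as.integer(q_levels),
              k_colors = as.integer(k_colors),
              crop_fraction = crop_fraction,
              cutoff_fraction = cutoff_fraction,
              trunk_dim = as.integer(trunk_dim), drop_path = drop_path,
              use_backbone = use_backbone, use_ffm = use_ffm,
              use_ccfm = use_ccfm, backbone = backbone,
              adapter_dim = adapter_dim)
  if (!cfg$use_backbone && !cfg$use_ffm && !cfg$use_ccfm)
    stop("at least one branch must be enabled", call. = FALSE)
  g <- cfg$input_size / cfg$patch
  stages <- length(cfg$depths)
  if (g != round(g))
    stop("input_size must be divisible by patch", call. = FALSE)
  for (s in seq_len(stages)) {
    if (g %% cfg$window != 0L)
      stop(sprintf("stage %d grid %d not divisible by window %d",
                   s, g, cfg$window), call. = FALSE)
    if (s < stages && g %% 2L != 0L)
      stop("grid side must be even before each merge", call. = FALSE)
    if (s < stages) g <- g %/% 2L
  }
  class(cfg) <- "leafcure_config"
  cfg
}

backbone_out_dim <- function(cfg) {
  if (is.function(cfg$backbone)) {
    if (is.null(cfg$adapter_dim))
      stop("adapter_dim must be set for a backbone adapter", call. = FALSE)
    return(as.integer(cfg$adapter_dim))
  }
  as.integer(cfg$embed_dim * 2^(length(cfg$depths) - 1L))
}

fused_dim <- function(cfg) {
  (if (cfg$use_backbone) backbone_out_dim(cfg) else 0L) +
    (if (cfg$use_ffm) cfg$d_spect else 0L) +
    (if (cfg$use_ccfm) cfg$d_color else 0L)
}

FFM_CHANNELS <- function(cfg) c(16L, 32L, 64L, cfg$d_spect)

#' Initialize the three-branch model
#'
#' @param config a [leafcure_config()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `leafcure_model` with fields `config`, `params`
#'   (flat named list of arrays) and `config_hash`.
#' @export
leafcure_model <- function(config = leafcure_config(), seed = 1L) {
  cfg <- config
  p <- list()
  withr::with_seed(seed, {
    if (cfg$use_backbone && !is.function(cfg$backbone)) {
      dpx <- 3L * cfg$patch^2
      p[["embed.w"]] <- init_mat(dpx, cfg$embed_dim)
      p[["embed.b"]] <- numeric(cfg$embed_dim)
      d <- cfg$embed_dim
      for (s in seq_along(cfg$depths)) {
        for (b in seq_len(cfg$depths[s])) {
          pre <- sprintf("s%d.b%d.", s, b)
          p[[paste0(pre, "ln1.g")]] <- rep(1, d)
          p[[paste0(pre, "ln1.b")]] <- numeric(d)
          p[[paste0(pre, "attn.w")]] <- init_mat(d, 3L * d)
          p[[paste0(pre, "attn.theta")]] <- log(10)
          bn <- init_bias_net(cfg$bias_hidden, sd = 0.2)
          p[[paste0(pre, "attn.bias.w1")]] <- bn$w1
          p[[paste0(pre, "attn.bias.b1")]] <- bn$b1
          p[[paste0(pre, "attn.bias.w2")]] <- bn$w2
          p[[paste0(pre, "attn.bias.b2")]] <- bn$b2
          p[[paste0(pre, "ln2.g")]] <- rep(1, d)
          p[[paste0(pre, "ln2.b")]] <- numeric(d)
          hid <- round(cfg$mlp_ratio * d)
          p[[paste0(pre, "mlp.w1")]] <- init_mat(d, hid, sqrt(2 / d))
          p[[paste0(pre, "mlp.b1")]] <- numeric(hid)
          p[[paste0(pre, "mlp.w2")]] <- init_mat(hid, d, sqrt(2 / hid))
          p[[paste0(pre, "mlp.b2")]] <- numeric(d)
        }
        if (s < length(cfg$depths)) {
          p[[sprintf("merge%d.w", s)]] <- init_mat(4L * d, 2L * d,
                                                   sqrt(1 / (2 * d)))
          p[[sprintf("merge%d.b", s)]] <- numeric(2L * d)
          d <- 2L * d
        }
      }
      p[["norm.g"]] <- rep(1, d)
      p[["norm.b"]] <- numeric(d)
    }
    if (cfg$use_ffm) {
      ch <- c(2L, FFM_CHANNELS(cfg))
      for (l in 1:4) {
        fan_in <- 9L * ch[l]
        p[[sprintf("ffm.c%d.w", l)]] <- init_mat(fan_in, ch[l + 1L],
                                                 sqrt(2 / fan_in))
        p[[sprintf("ffm.c%d.b", l)]] <- numeric(ch[l + 1L])
      }
    }
    if (cfg$use_ccfm) {
      din <- 5L * cfg$k_colors
      p[["ccfm.w"]] <- init_mat(din, cfg$d_color, sqrt(2 / din))
      p[["ccfm.b"]] <- numeric(cfg$d_color)
    }
    dfuse <- fused_dim(cfg)
    p[["trunk.w"]] <- init_mat(dfuse, cfg$trunk_dim, sqrt(2 / dfuse))
    p[["trunk.b"]] <- numeric(cfg$trunk_dim)
    for (hn in c("heady", "headb", "headd")) {
      k <- c(heady = N_YELLOWING, headb = N_BROWNING, headd = N_DRYING)[[hn]]
      p[[paste0(hn, ".w")]] <- init_mat(cfg$trunk_dim, k)
      p[[paste0(hn, ".b")]] <- numeric(k)
    }
  })
  structure(list(config = cfg, params = p, config_hash = config_hash(cfg)),
            class = "leafcure_model")
}

config_hash <- function(cfg) {
  cfg$backbone <- if (is.function(cfg$backbone)) "adapter" else cfg$backbone
  rlang::hash(cfg)
}

#' @export
print.leafcure_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  br <- c(if (x$config$use_backbone) "backbone",
          if (x$config$use_ffm) "FFM", if (x$config$use_ccfm) "CCFM")
  cat(sprintf("<leafcure_model: %s; %d parameters; input %dpx>\n",
              paste(br, collapse = " + "), np, x$config$input_size))
  invisible(x)
}

#' Count of trainable parameters
#' @param model a `leafcure_model`.
#' @return integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---------------------------------------------------------------------------
# Backbone forward/backward

part_windows <- function(y, widx) {
  n <- nrow(widx); nw <- ncol(widx); d <- ncol(y)
  aperm(array(y[as.vector(widx), ], c(n, nw, d)), c(1, 3, 2))
}

unpart_windows <- function(o, widx, ntok) {
  n <- dim(o)[1]; d <- dim(o)[2]; nw <- dim(o)[3]
  m <- matrix(aperm(o, c(1, 3, 2)), n * nw, d)
  out <- matrix(0, ntok, d)
  out[as.vector(widx), ] <- m
  out
}

block_fwd <- function(tok, g, cfg, p, pre, train) {
  cache <- list(tok_in = tok, g = g)
  ln1 <- layernorm_fwd(tok, p[[paste0(pre, "ln1.g")]],
                       p[[paste0(pre, "ln1.b")]])
  widx <- window_index(g, cfg$window)
  btab <- bias_tables(cfg$window)
  bparams <- list(w1 = p[[paste0(pre, "attn.bias.w1")]],
                  b1 = p[[paste0(pre, "attn.bias.b1")]],
                  w2 = p[[paste0(pre, "attn.bias.w2")]],
                  b2 = p[[paste0(pre, "attn.bias.b2")]])
  bnet <- bias_net_fwd(btab$offsets, bparams)
  n <- nrow(widx)
  bmat <- matrix(bnet$out[btab$index], n, n)
  theta <- p[[paste0(pre, "attn.theta")]][1]
  inv_tau <- exp(min(theta, log(100)))
  fcube <- part_windows(ln1$y, widx)
  att <- cpp_win_attn_fwd(fcube, p[[paste0(pre, "attn.w")]], inv_tau, bmat)
  attn_tok <- unpart_windows(att$O, widx, nrow(tok))
  keep1 <- if (train && cfg$drop_path > 0) stats::runif(1) >= cfg$drop_path
           else TRUE
  sc1 <- if (train && cfg$drop_path > 0 && keep1) 1 / (1 - cfg$drop_path)
         else 1
  tok1 <- if (keep1) tok + attn_tok * sc1 else tok
  ln2 <- layernorm_fwd(tok1, p[[paste0(pre, "ln2.g")]],
                       p[[paste0(pre, "ln2.b")]])
  h_pre <- linear_fwd(ln2$y, p[[paste0(pre, "mlp.w1")]],
                      p[[paste0(pre, "mlp.b1")]])
  h <- relu(h_pre)
  m_out <- linear_fwd(h, p[[paste0(pre, "mlp.w2")]],
                      p[[paste0(pre, "mlp.b2")]])
  keep2 <- if (train && cfg$drop_path > 0) stats::runif(1) >= cfg$drop_path
           else TRUE
  sc2 <- if (train && cfg$drop_path > 0 && keep2) 1 / (1 - cfg$drop_path)
         else 1
  tok2 <- if (keep2) tok1 + m_out * sc2 else tok1
  cache <- c(cache, list(ln1 = ln1, widx = widx, btab = btab, bnet = bnet,
                         bmat = bmat, inv_tau = inv_tau, theta = theta,
                         fcube = fcube, att = att, keep1 = keep1, sc1 = sc1,
                         tok1 = tok1, ln2 = ln2, h_pre = h_pre, h = h,
                         keep2 = keep2, sc2 = sc2))
  list(tok = tok2, cache = cache)
}

block_bwd <- function(dtok2, cache, cfg, p, pre, acc) {
  dtok1 <- dtok2
  if (cache$keep2) {
    dm <- dtok2 * cache$sc2
    g2 <- linear_bwd(cache$h, p[[paste0(pre, "mlp.w2")]], dm)
    addg(acc, paste0(pre, "mlp.w2"), g2$dw)
    addg(acc, paste0(pre, "mlp.b2"), g2$db)
    dh <- g2$dx * (cache$h_pre > 0)
    g1 <- linear_bwd(cache$ln2$y, p[[paste0(pre, "mlp.w1")]], dh)
    addg(acc, paste0(pre, "mlp.w1"), g1$dw)
    addg(acc, paste0(pre, "mlp.b1"), g1$db)
    lb <- layernorm_bwd(cache$ln2, p[[paste0(pre, "ln2.g")]], g1$dx)
    addg(acc, paste0(pre, "ln2.g"), lb$dg)
    addg(acc, paste0(pre, "ln2.b"), lb$db)
    dtok1 <- dtok1 + lb$dx
  }
  dtok <- dtok1
  if (cache$keep1) {
    dattn_tok <- dtok1 * cache$sc1
    do_cube <- part_windows(dattn_tok, cache$widx)
    ab <- cpp_win_attn_bwd(cache$fcube, p[[paste0(pre, "attn.w")]],
                           cache$inv_tau, cache$att$Qr, cache$att$Kr,
                           cache$att$V, cache$att$Qn, cache$att$Kn,
                           cache$att$C, cache$att$A, do_cube)
    addg(acc, paste0(pre, "attn.w"), ab$dW)
    if (cache$theta < log(100))
      addg(acc, paste0(pre, "attn.theta"), ab$d_invtau * cache$inv_tau)
    dbias_vals <- rowsum(as.vector(ab$dB),
                         group = as.vector(cache$btab$index))
    dout <- numeric(cache$btab$n_off)
    dout[as.integer(rownames(dbias_vals))] <- dbias_vals[, 1]
    bg <- bias_net_bwd(cache$bnet, list(
      w1 = p[[paste0(pre, "attn.bias.w1")]],
      b1 = p[[paste0(pre, "attn.bias.b1")]],
      w2 = p[[paste0(pre, "attn.bias.w2")]],
      b2 = p[[paste0(pre, "attn.bias.b2")]]), dout)
    addg(acc, paste0(pre, "attn.bias.w1"), bg$w1)
    addg(acc, paste0(pre, "attn.bias.b1"), bg$b1)
    addg(acc, paste0(pre, "attn.bias.w2"), bg$w2)
    addg(acc, paste0(pre, "attn.bias.b2"), bg$b2)
    dln1y <- unpart_windows(ab$dF, cache$widx, nrow(dtok1))
    lb1 <- layernorm_bwd(cache$ln1, p[[paste0(pre, "ln1.g")]], dln1y)
    addg(acc, paste0(pre, "ln1.g"), lb1$dg)
    addg(acc, paste0(pre, "ln1.b"), lb1$db)
    dtok <- dtok + lb1$dx
  }
  dtok
}

addg <- function(acc, name, val) {
  cur <- acc$g[[name]]
  acc$g[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

backbone_fwd <- function(patches, cfg, p, train) {
  tok <- linear_fwd(patches, p[["embed.w"]], p[["embed.b"]])
  g <- cfg$input_size %/% cfg$patch
  caches <- list()
  k <- 0L
  for (s in seq_along(cfg$depths)) {
    for (b in seq_len(cfg$depths[s])) {
      res <- block_fwd(tok, g, cfg, p, sprintf("s%d.b%d.", s, b), train)
      tok <- res$tok
      k <- k + 1L
      caches[[k]] <- list(kind = "block", pre = sprintf("s%d.b%d.", s, b),
                          cache = res$cache)
    }
    if (s < length(cfg$depths)) {
      k <- k + 1L
      caches[[k]] <- list(kind = "merge", s = s, tok_in = tok, g = g)
      tok <- patch_split_merge(tok, g, p[[sprintf("merge%d.w", s)]],
                               p[[sprintf("merge%d.b", s)]])
      g <- g %/% 2L
    }
  }
  lnf <- layernorm_fwd(tok, p[["norm.g"]], p[["norm.b"]])
  f_img <- colMeans(lnf$y)
  list(f_img = f_img, caches = caches, lnf = lnf, tokens_last = tok,
       grid_last = g, patches = patches)
}

backbone_bwd <- function(df_img, fwd, cfg, p, acc,
                         stop_at_tokens = FALSE) {
  ntok <- nrow(fwd$lnf$y)
  dy <- matrix(rep(df_img / ntok, each = ntok), ntok, length(df_img))
  lb <- layernorm_bwd(fwd$lnf, p[["norm.g"]], dy)
  addg(acc, "norm.g", lb$dg)
  addg(acc, "norm.b", lb$db)
  dtok <- lb$dx
  if (stop_at_tokens) return(dtok)
  for (k in rev(seq_along(fwd$caches))) {
    entry <- fwd$caches[[k]]
    if (entry$kind == "merge") {
      mb <- merge_bwd(entry$tok_in, entry$g,
                      p[[sprintf("merge%d.w", entry$s)]], dtok)
      addg(acc, sprintf("merge%d.w", entry$s), mb$dw)
      addg(acc, sprintf("merge%d.b", entry$s), mb$db)
      dtok <- mb$dtokens
    } else {
      dtok <- block_bwd(dtok, entry$cache, cfg, p, entry$pre, acc)
    }
  }
  ge <- linear_bwd(fwd$patches, p[["embed.w"]], dtok)
  addg(acc, "embed.w", ge$dw)
  addg(acc, "embed.b", ge$db)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# FFM: 4-layer convolutional spectral feature extractor

ffm_input <- function(image, cfg) {
  gray <- to_grayscale(image) / 255
  spectrum_channels(dft2(gray))
}

#' Extract the spectral feature from a Fourier spectrum
#'
#' Four convolutional layers (3x3 kernels, stride-2 downsampling, ReLU),
#' channel plan 2 -> 16 -> 32 -> 64 -> `d_spect`, consuming the real and
#' imaginary spectrum planes as two channels, followed by global average
#' pooling. Differentiable end to end.
#'
#' @param spectrum a `spectrum_plane` from [dft2()] (spatial size >= 32).
#' @param model a `leafcure_model` whose config enables the FFM branch (the
#'   layer weights live in `model$params`).
#' @return numeric feature vector of length `d_spect`.
#' @export
spectral_feature_extractor <- function(spectrum, model) {
  x <- spectrum_channels(spectrum)
  ffm_fwd(x, model$params)$f
}

ffm_fwd <- function(x, p) {
  if (dim(x)[1] < 32L || dim(x)[2] < 32L)
    stop("spectral input must be at least 32 x 32", call. = FALSE)
  xs <- list(x)
  pre <- list()
  for (l in 1:4) {
    z <- cpp_conv2d_fwd(xs[[l]], p[[sprintf("ffm.c%d.w", l)]],
                        p[[sprintf("ffm.c%d.b", l)]], 3L, 2L, 1L)
    pre[[l]] <- z
    a <- z
    a[a < 0] <- 0
    xs[[l + 1L]] <- a
  }
  last <- xs[[5L]]
  f <- apply(last, 3L, mean)
  list(f = f, xs = xs, pre = pre)
}

ffm_bwd <- function(df, fwd, p, acc) {
  last <- fwd$xs[[5L]]
  dm <- dim(last)
  ga <- array(rep(df / (dm[1] * dm[2]), each = dm[1] * dm[2]), dim = dm)
  for (l in 4:1) {
    gz <- ga * (fwd$pre[[l]] > 0)
    cb <- cpp_conv2d_bwd(fwd$xs[[l]], p[[sprintf("ffm.c%d.w", l)]],
                         3L, 2L, 1L, gz, need_dx = l > 1L)
    addg(acc, sprintf("ffm.c%d.w", l), cb$dw)
    addg(acc, sprintf("ffm.c%d.b", l), as.vector(cb$db))
    ga <- cb$dx
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# CCFM: single fully connected layer on the serialized colour descriptor

#' Extract the colour feature from a common-colour descriptor
#'
#' A single fully connected layer plus ReLU applied to the serialized
#' descriptor (per slot: colour triple scaled to 0-1, relative frequency,
#' normalized first-appearance rank).
#'
#' @param descriptor a `common_color_descriptor`.
#' @param model a `leafcure_model` whose config enables the CCFM branch.
#' @return numeric feature vector of length `d_color`.
#' @export
color_feature_extractor <- function(descriptor, model) {
  v <- descriptor_vector(descriptor)
  if (length(v) != nrow(model$params[["ccfm.w"]]))
    stop(sprintf("descriptor vector length %d does not match weights (%d)",
                 length(v), nrow(model$params[["ccfm.w"]])), call. = FALSE)
  ccfm_fwd(v, model$params)$f
}

ccfm_fwd <- function(v, p) {
  z <- linear_fwd(matrix(v, 1L), p[["ccfm.w"]], p[["ccfm.b"]])
  f <- as.vector(z)
  f[f < 0] <- 0
  list(f = f, z = as.vector(z), v = v)
}

ccfm_bwd <- function(df, fwd, p, acc) {
  dz <- df * (fwd$z > 0)
  g <- linear_bwd(matrix(fwd$v, 1L), p[["ccfm.w"]], matrix(dz, 1L))
  addg(acc, "ccfm.w", g$dw)
  addg(acc, "ccfm.b", g$db)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Fusion head

#' Fuse branch features and predict the three states
#'
#' Concatenates the available branch features, applies the shared fully
#' connected trunk (ReLU) and three softmax heads of sizes 7, 6 and 9,
#' returning one probability distribution per state.
#'
#' @param f_img backbone feature vector (or NULL if the branch is off).
#' @param f_spect spectral feature vector (or NULL).
#' @param f_color colour feature vector (or NULL).
#' @param model a `leafcure_model` holding the head weights.
#' @return object of class `state_prediction`: list with probability
#'   vectors `p_yellow` (7), `p_brown` (6), `p_dry` (9).
#' @export
fuse_and_classify <- function(f_img, f_spect, f_color, model) {
  for (nm in c("f_img", "f_spect", "f_color")) {
    v <- get(nm)
    if (!is.null(v) && any(!is.finite(v)))
      stop(sprintf("non-finite values in branch feature `%s`", nm),
           call. = FALSE)
  }
  head_fwd(c(f_img, f_spect, f_color), model$params)$pred
}

head_fwd <- function(feats, p) {
  z_pre <- linear_fwd(matrix(feats, 1L), p[["trunk.w"]], p[["trunk.b"]])
  z <- relu(z_pre)
  lg <- list(y = linear_fwd(z, p[["heady.w"]], p[["heady.b"]]),
             b = linear_fwd(z, p[["headb.w"]], p[["headb.b"]]),
             d = linear_fwd(z, p[["headd.w"]], p[["headd.b"]]))
  pred <- structure(list(p_yellow = as.vector(softmax_rows(lg$y)),
                         p_brown = as.vector(softmax_rows(lg$b)),
                         p_dry = as.vector(softmax_rows(lg$d))),
                    class = "state_prediction")
  list(pred = pred, z = z, z_pre = z_pre, feats = feats, logits = lg)
}

head_bwd <- function(dlogits, fwd, p, acc) {
  dz <- matrix(0, 1L, ncol(fwd$z))
  for (hn in c("y", "b", "d")) {
    key <- c(y = "heady", b = "headb", d = "headd")[[hn]]
    g <- linear_bwd(fwd$z, p[[paste0(key, ".w")]],
                    matrix(dlogits[[hn]], 1L))
    addg(acc, paste0(key, ".w"), g$dw)
    addg(acc, paste0(key, ".b"), g$db)
    dz <- dz + g$dx
  }
  dz <- dz * (fwd$z_pre > 0)
  g <- linear_bwd(matrix(fwd$feats, 1L), p[["trunk.w"]], dz)
  addg(acc, "trunk.w", g$dw)
  addg(acc, "trunk.b", g$db)
  as.vector(g$dx)
}

#' @export
print.state_prediction <- function(x, ...) {
  cat(sprintf(
    "<state_prediction: yellowing=%d (%.2f) browning=%d (%.2f) drying=%d (%.2f)>\n",
    which.max(x$p_yellow) - 1L, max(x$p_yellow),
    which.max(x$p_brown) - 1L, max(x$p_brown),
    which.max(x$p_dry) - 1L, max(x$p_dry)))
  invisible(x)
}

#' Joint multi-state cross-entropy loss
#'
#' Sum of the three per-state cross-entropies (weights configurable), the
#' objective of joint training of the multi-label head. Zero exactly when
#' each head puts probability one on the true class.
#'
#' @param pred a `state_prediction`.
#' @param label a [state_label()].
#' @param weights positive length-3 weights (yellowing, browning, drying).
#' @return non-negative scalar.
#' @export
multi_state_loss <- function(pred, label, weights = c(1, 1, 1)) {
  stopifnot(inherits(pred, "state_prediction"))
  stopifnot(inherits(label, "state_label"))
  eps <- 1e-12
  weights[1] * -log(pred$p_yellow[label$yellowing + 1L] + eps) +
    weights[2] * -log(pred$p_brown[label$browning + 1L] + eps) +
    weights[3] * -log(pred$p_dry[label$drying + 1L] + eps)
}

# ---------------------------------------------------------------------------
# Whole-model forward/backward on one preprocessed sample.
# A sample is list(patches, spect (H x W x 2 or NULL), cvec (descriptor
# vector or NULL), image (raw array; needed only for a backbone adapter)).

model_forward <- function(model, sample, train = FALSE) {
  cfg <- model$config
  p <- model$params
  f_img <- NULL; bb <- NULL; ff <- NULL; cf <- NULL
  if (cfg$use_backbone) {
    if (is.function(cfg$backbone)) {
      f_img <- cfg$backbone(sample$image)
    } else {
      bb <- backbone_fwd(sample$patches, cfg, p, train)
      f_img <- bb$f_img
    }
  }
  f_spect <- NULL
  if (cfg$use_ffm) {
    ff <- ffm_fwd(sample$spect, p)
    f_spect <- ff$f
  }
  f_color <- NULL
  if (cfg$use_ccfm) {
    cf <- ccfm_fwd(sample$cvec, p)
    f_color <- cf$f
  }
  hd <- head_fwd(c(f_img, f_spect, f_color), p)
  list(pred = hd$pred, head = hd, bb = bb, ff = ff, cf = cf,
       dims = c(img = length(f_img), spect = length(f_spect),
                color = length(f_color)))
}

# dlogits: list(y =, b =, d =) gradients at the three logit vectors
model_backward <- function(model, fwd, dlogits, acc,
                           stop_at_tokens = FALSE) {
  cfg <- model$config
  p <- model$params
  dfeats <- head_bwd(dlogits, fwd$head, p, acc)
  off <- 0L
  dtok <- NULL
  if (fwd$dims[["img"]] > 0L) {
    d_img <- dfeats[(off + 1L):(off + fwd$dims[["img"]])]
    off <- off + fwd$dims[["img"]]
    if (!is.null(fwd$bb))
      dtok <- backbone_bwd(d_img, fwd$bb, cfg, p, acc, stop_at_tokens)
  }
  if (fwd$dims[["spect"]] > 0L) {
    d_sp <- dfeats[(off + 1L):(off + fwd$dims[["spect"]])]
    off <- off + fwd$dims[["spect"]]
    ffm_bwd(d_sp, fwd$ff, p, acc)
  }
  if (fwd$dims[["color"]] > 0L) {
    d_co <- dfeats[(off + 1L):(off + fwd$dims[["color"]])]
    ccfm_bwd(d_co, fwd$cf, p, acc)
  }
  invisible(dtok)
}

# Preprocess one raw image array into the per-branch inputs
preprocess_sample <- function(image, cfg) {
  if (dim(image)[1] != cfg$input_size || dim(image)[2] != cfg$input_size)
    image <- EBImage::resize(image, w = cfg$input_size, h = cfg$input_size)
  list(image = image,
       patches = if (cfg$use_backbone && !is.function(cfg$backbone))
         patch_split(image, cfg$patch) else NULL,
       spect = if (cfg$use_ffm) ffm_input(image, cfg) else NULL,
       cvec = if (cfg$use_ccfm) ccfm_input(image, cfg) else NULL)
}
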