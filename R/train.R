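#' Training recipe configuration
#'
#' Defaults follow the fine-tuning recipe used for the curing-state task:
#' AdamW, cosine learning-rate schedule from `base_lr` down to `end_lr`
#' with a linear warmup from `warmup_lr` over `decay_epoch` epochs, batch
#' size 8, gradient norm clipped at 1, stochastic depth 0.1 on backbone
#' blocks, RandAugment with magnitude 9 and magnitude noise sd 0.5.
#'
#' @param warmup_lr,base_lr,end_lr learning-rate schedule anchors.
#' @param batch_size images per optimizer step.
#' @param decay_epoch warmup length in epochs (the cosine decay then spans
#'   the remaining steps).
#' @param schedule `"cosine"` (only supported schedule).
#' @param optimizer `"adamw"` (only supported optimizer).
#' @param drop_path stochastic-depth rate applied to backbone blocks.
#' @param grad_clip global gradient-norm clip.
#' @param input_size optional override of the model input side in pixels;
#'   NULL inherits the model configuration.
#' @param randaugment_magnitude,randaugment_std RandAugment magnitude (0-10
#'   scale) and the sd of its per-image Gaussian magnitude noise.
#' @param augment logical; apply RandAugment during training. Disable for
#'   experiments whose labels are colour-coded into the pixels.
#' @param augment_ops character vector of RandAugment op names to draw
#'   from; the default is the full set. A geometric-only subset
#'   (`c("translate_x", "translate_y")`) preserves planted colour labels
#'   while still diversifying spectral phase.
#' @param epochs training epochs.
#' @param weight_decay decoupled AdamW weight decay.
#' @param state_weights loss weights of (yellowing, browning, drying).
#' @param seed integer seed making the run reproducible end to end.
#' @return list of class `train_config`.
#' @export
train_config <- function(warmup_lr = 2e-8, base_lr = 2e-4, end_lr = 2e-7,
                         batch_size = 8L, decay_epoch = 5L,
                         schedule = "cosine", optimizer = "adamw",
                         drop_path = 0.1, grad_clip = 1,
                         input_size = NULL, randaugment_magnitude = 9,
                         randaugment_std = 0.5, augment = TRUE,
                         augment_ops = RAND_AUGMENT_OPS,
                         epochs = 30L, weight_decay = 0.01,
                         state_weights = c(1, 1, 1), seed = 1L) {
  stopifnot(identical(schedule, "cosine"), identical(optimizer, "adamw"))
  structure(list(warmup_lr = warmup_lr, base_lr = base_lr, end_lr = end_lr,
                 batch_size = as.integer(batch_size),
                 decay_epoch = as.integer(decay_epoch), schedule = schedule,
                 optimizer = optimizer, drop_path = drop_path,
                 grad_clip = grad_clip, input_size = input_size,
                 randaugment_magnitude = randaugment_magnitude,
                 randaugment_std = randaugment_std, augment = augment,
                 augment_ops = augment_ops,
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 state_weights = state_weights, seed = as.integer(seed)),
            class = "train_config")
}

lr_at <- function(step, total, warmup, tc) {
  if (warmup > 0 && step <= warmup)
    return(tc$warmup_lr + (tc$base_lr - tc$warmup_lr) * step / warmup)
  prog <- (step - warmup) / max(total - warmup, 1L)
  tc$end_lr + 0.5 * (tc$base_lr - tc$end_lr) * (1 + cos(pi * prog))
}

# RandAugment-style photometric/geometric ops on a 0-255 RGB array.
RAND_AUGMENT_OPS <- c("identity", "brightness", "contrast", "saturation",
                      "translate_x", "translate_y")

apply_randaugment <- function(px, magnitude, std,
                              op_set = RAND_AUGMENT_OPS) {
  m <- min(max(rnorm(1, magnitude, std), 0), 10) / 10
  ops <- sample(op_set, 2L, replace = length(op_set) < 2L)
  for (op in ops) {
    dir <- sample(c(-1, 1), 1L)
    px <- switch(op,
      identity = px,
      brightness = px + dir * m * 60,
      contrast = (px - mean(px)) * (1 + dir * m * 0.6) + mean(px),
      saturation = {
        gray <- to_grayscale(px)
        a <- m * 0.6
        for (c in 1:3) px[, , c] <- (1 - a) * px[, , c] + a * gray
        px
      },
      translate_x = shift_image(px, 0L, dir * round(m * 0.25 * dim(px)[2])),
      translate_y = shift_image(px, dir * round(m * 0.25 * dim(px)[1]), 0L))
  }
  clip255(px)
}

shift_image <- function(px, dy, dx) {
  h <- dim(px)[1]; w <- dim(px)[2]
  ys <- pmin(pmax(seq_len(h) - dy, 1L), h)
  xs <- pmin(pmax(seq_len(w) - dx, 1L), w)
  px[ys, xs, , drop = FALSE]
}

load_training_set <- function(manifest, cfg) {
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing))
    stop(sprintf("missing image files (%d): %s", length(missing),
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_image(manifest$path[i], size = cfg$input_size)
    list(image = img,
         label = state_label(manifest$yellowing[i], manifest$browning[i],
                             manifest$drying[i]))
  })
}

#' Train the three-branch recognizer on a labelled manifest
#'
#' Joint training of the multi-label head: the loss is the sum of the three
#' per-state cross-entropies. Optimization is AdamW with cosine schedule,
#' warmup, global gradient-norm clipping and stochastic depth, all taken
#' from the [train_config()]. Fully reproducible given the config seed
#' (data order, augmentation and stochastic-depth streams all derive from
#' it).
#'
#' @param manifest path of a manifest CSV, or a data.frame from
#'   [read_manifest()].
#' @param model_config a [leafcure_config()].
#' @param tc a [train_config()].
#' @param model optional pre-initialized `leafcure_model` to continue from.
#' @param track_accuracy compute per-state training accuracy each epoch.
#' @param verbose print one line per epoch.
#' @return object of class `leafcure_fit`: list with `model` (trained),
#'   `history` (data.frame epoch/loss/lr and optional accuracies), `tc`.
#' @export
train_model <- function(manifest, model_config = leafcure_config(),
                        tc = train_config(), model = NULL,
                        track_accuracy = FALSE, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  cfg <- model_config
  if (!is.null(tc$input_size)) cfg$input_size <- as.integer(tc$input_size)
  cfg$drop_path <- tc$drop_path
  if (is.null(model)) model <- leafcure_model(cfg, seed = tc$seed)
  else cfg <- model$config
  p <- model$params
  dat <- load_training_set(manifest, cfg)
  n <- length(dat)
  spe <- ceiling(n / tc$batch_size)
  total <- tc$epochs * spe
  warmup <- min(tc$decay_epoch * spe, total - 1L)
  no_decay <- grep("\\.(b|b1|b2|g)$|theta", names(p), value = TRUE)
  opt <- adamw_init(p)
  history <- vector("list", tc$epochs)
  base_samples <- NULL
  if (!tc$augment)
    base_samples <- lapply(dat, function(d) preprocess_sample(d$image, cfg))
  step <- 0L
  withr::with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bs in seq_len(spe)) {
        idx <- ord[((bs - 1L) * tc$batch_size + 1L):
                     min(bs * tc$batch_size, n)]
        acc <- new.env(parent = emptyenv())
        acc$g <- list()
        bl <- 0
        for (i in idx) {
          smp <- if (is.null(base_samples)) {
            aug <- apply_randaugment(dat[[i]]$image,
                                     tc$randaugment_magnitude,
                                     tc$randaugment_std, tc$augment_ops)
            preprocess_sample(aug, cfg)
          } else base_samples[[i]]
          fwd <- model_forward(model, smp, train = TRUE)
          lab <- dat[[i]]$label
          bl <- bl + multi_state_loss(fwd$pred, lab, tc$state_weights)
          dl <- list(
            y = tc$state_weights[1] *
              (fwd$pred$p_yellow - onehot(lab$yellowing, N_YELLOWING)) /
              length(idx),
            b = tc$state_weights[2] *
              (fwd$pred$p_brown - onehot(lab$browning, N_BROWNING)) /
              length(idx),
            d = tc$state_weights[3] *
              (fwd$pred$p_dry - onehot(lab$drying, N_DRYING)) /
              length(idx))
          model_backward(model, fwd, dl, acc)
        }
        gn <- global_norm(acc$g)
        if (is.finite(gn) && gn > tc$grad_clip)
          acc$g <- lapply(acc$g, function(x) x * (tc$grad_clip / gn))
        step <- step + 1L
        res <- adamw_step(model$params, acc$g, opt,
                          lr = lr_at(step, total, warmup, tc),
                          weight_decay = tc$weight_decay,
                          no_decay = no_decay)
        model$params <- res$params
        opt <- res$state
        ep_loss <- ep_loss + bl / length(idx)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / spe,
                        lr = lr_at(step, total, warmup, tc))
      if (track_accuracy) {
        tr <- predict_samples(model,
                              if (is.null(base_samples))
                                lapply(dat, function(d)
                                  preprocess_sample(d$image, cfg))
                              else base_samples)
        truth <- labels_frame(dat)
        row$acc_yellowing <- 100 * mean(tr$yellowing == truth$yellowing)
        row$acc_browning <- 100 * mean(tr$browning == truth$browning)
        row$acc_drying <- 100 * mean(tr$drying == truth$drying)
      }
      history[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %.2e%s", ep, row$loss,
                        row$lr,
                        if (track_accuracy)
                          sprintf("  acc %.1f/%.1f/%.1f", row$acc_yellowing,
                                  row$acc_browning, row$acc_drying)
                        else ""))
    }
  })
  structure(list(model = model, history = do.call(rbind, history), tc = tc),
            class = "leafcure_fit")
}

onehot <- function(k, n) {
  v <- numeric(n)
  v[k + 1L] <- 1
  v
}

labels_frame <- function(dat) {
  data.frame(yellowing = vapply(dat, function(d) d$label$yellowing,
                                integer(1)),
             browning = vapply(dat, function(d) d$label$browning,
                               integer(1)),
             drying = vapply(dat, function(d) d$label$drying, integer(1)))
}

predict_samples <- function(model, samples) {
  out <- lapply(samples, function(s) model_forward(model, s, train = FALSE))
  data.frame(
    yellowing = vapply(out, function(o) which.max(o$pred$p_yellow) - 1L,
                       integer(1)),
    browning = vapply(out, function(o) which.max(o$pred$p_brown) - 1L,
                      integer(1)),
    drying = vapply(out, function(o) which.max(o$pred$p_dry) - 1L,
                    integer(1)))
}

#' @export
print.leafcure_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<leafcure_fit: %d epochs, final loss %.4f>\n",
              nrow(h), h$loss[nrow(h)]))
  invisible(x)
}

#' Predict curing states for images
#'
#' @param object a trained `leafcure_model` (or a `leafcure_fit`).
#' @param newdata an H x W x 3 array, a list of such arrays, or a manifest
#'   data.frame with a `path` column.
#' @param ... unused.
#' @return list with `classes` (data.frame of argmax class indices per
#'   state) and `probabilities` (list of `state_prediction`).
#' @export
predict.leafcure_model <- function(object, newdata, ...) {
  model <- object
  cfg <- model$config
  imgs <- if (is.data.frame(newdata)) {
    lapply(newdata$path, load_image, size = cfg$input_size)
  } else if (is.list(newdata) && !is.array(newdata)) {
    newdata
  } else {
    list(newdata)
  }
  samples <- lapply(imgs, preprocess_sample, cfg = cfg)
  preds <- lapply(samples, function(s)
    model_forward(model, s, train = FALSE)$pred)
  classes <- data.frame(
    yellowing = vapply(preds, function(p) which.max(p$p_yellow) - 1L,
                       integer(1)),
    browning = vapply(preds, function(p) which.max(p$p_brown) - 1L,
                      integer(1)),
    drying = vapply(preds, function(p) which.max(p$p_dry) - 1L, integer(1)))
  list(classes = classes, probabilities = preds)
}

#' @export
predict.leafcure_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Save a model checkpoint
#'
#' Single-file archive of the named parameter groups, the configuration and
#' its hash; [load_checkpoint()] refuses files whose stored hash does not
#' match the stored configuration.
#'
#' @param model a `leafcure_model` or `leafcure_fit`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "leafcure_fit")) model <- model$model
  cfg <- model$config
  if (is.function(cfg$backbone)) cfg$backbone <- "adapter"
  saveRDS(list(params = model$params, config = cfg,
               config_hash = model$config_hash), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param backbone optional adapter function if the checkpoint was trained
#'   with one.
#' @return a `leafcure_model`.
#' @export
load_checkpoint <- function(path, backbone = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$params) || is.null(obj$config))
    stop("corrupt checkpoint: missing params/config", call. = FALSE)
  h <- config_hash(obj$config)
  if (!identical(h, obj$config_hash))
    stop(sprintf(
      "checkpoint config hash mismatch: stored %s, recomputed %s",
      obj$config_hash, h), call. = FALSE)
  cfg <- obj$config
  if (identical(cfg$backbone, "adapter")) {
    if (is.null(backbone))
      stop("checkpoint used a backbone adapter; pass `backbone`",
           call. = FALSE)
    cfg$backbone <- backbone
  }
  class(cfg) <- "leafcure_config"
  structure(list(config = cfg, params = obj$params,
                 config_hash = obj$config_hash), class = "leafcure_model")
}

#' Stratified train/test split of a manifest
#'
#' @param manifest data.frame from [read_manifest()].
#' @param test_fraction fraction of rows held out.
#' @param stratify_by column used for stratification.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
split_manifest <- function(manifest, test_fraction = 0.3,
                           stratify_by = "drying", seed = 1L) {
  withr::with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(manifest)),
                                    manifest[[stratify_by]]), function(ix) {
      sample(ix, round(length(ix) * test_fraction))
    }), use.names = FALSE)
  })
  list(train = manifest[-test_idx, , drop = FALSE],
       test = manifest[test_idx, , drop = FALSE])
}
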