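#' Gradient-weighted class activation map for one state head
#'
#' Grad-CAM on the last backbone token grid: the gradient of the chosen
#' class logit with respect to the final-stage token features is averaged
#' per channel to weight the activation channels; the rectified weighted
#' sum, min-max normalized to [0, 1] and upsampled to the input size, shows
#' where the model looks when predicting that state (brown blotches for
#' browning, leaf texture for drying).
#'
#' @param model a trained `leafcure_model` using the reference backbone.
#' @param image H x W x 3 array (0-255).
#' @param state `"yellowing"`, `"browning"` or `"drying"`.
#' @param class_index class whose logit is explained (0-based); default the
#'   predicted class.
#' @param out_png optional path; if given, an overlay PNG is written.
#' @return object of class `saliency_map`: list with `map` (input-size
#'   matrix in [0, 1]), `map_grid` (token-grid resolution matrix), `state`,
#'   `class_index`, `overlay` (H x W x 3 array in [0, 1]).
#' @export
saliency_map <- function(model, image, state = c("yellowing", "browning",
                                                 "drying"),
                         class_index = NULL, out_png = NULL) {
  state <- match.arg(state)
  cfg <- model$config
  if (!cfg$use_backbone || is.function(cfg$backbone))
    stop("saliency needs the reference backbone's feature grid",
         call. = FALSE)
  k <- c(yellowing = N_YELLOWING, browning = N_BROWNING,
         drying = N_DRYING)[[state]]
  smp <- preprocess_sample(image, cfg)
  fwd <- model_forward(model, smp, train = FALSE)
  pvec <- switch(state, yellowing = fwd$pred$p_yellow,
                 browning = fwd$pred$p_brown, drying = fwd$pred$p_dry)
  if (is.null(class_index)) class_index <- which.max(pvec) - 1L
  check_number(class_index, "class_index", 0, k - 1L, integer = TRUE)
  dl <- list(y = numeric(N_YELLOWING), b = numeric(N_BROWNING),
             d = numeric(N_DRYING))
  key <- c(yellowing = "y", browning = "b", drying = "d")[[state]]
  dl[[key]][class_index + 1L] <- 1
  acc <- new.env(parent = emptyenv())
  acc$g <- list()
  dtok <- model_backward(model, fwd, dl, acc, stop_at_tokens = TRUE)
  tok <- fwd$bb$tokens_last
  g <- fwd$bb$grid_last
  alpha <- colMeans(dtok)
  cam <- as.vector(tok %*% alpha)
  cam[cam < 0] <- 0
  # tokens are in row-major raster order
  grid <- matrix(cam, g, g, byrow = TRUE)
  rng <- range(grid)
  grid_n <- if (rng[2] > rng[1]) (grid - rng[1]) / (rng[2] - rng[1])
            else grid * 0
  h <- dim(smp$image)[1]; w <- dim(smp$image)[2]
  map <- EBImage::resize(grid_n, w = h, h = w)
  map[map < 0] <- 0
  map[map > 1] <- 1
  base <- smp$image / 255
  overlay <- base * 0.5
  overlay[, , 1] <- overlay[, , 1] + 0.5 * map
  overlay[, , 3] <- overlay[, , 3] + 0.5 * (1 - map) * 0.3
  overlay[overlay > 1] <- 1
  if (!is.null(out_png)) png::writePNG(overlay, out_png)
  structure(list(map = map, map_grid = grid_n, state = state,
                 class_index = as.integer(class_index), overlay = overlay),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map %s class %d, %d x %d>\n", x$state,
              x$class_index, nrow(x$map), ncol(x$map)))
  invisible(x)
}
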