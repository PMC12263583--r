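#' @useDynLib leafcure, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qnorm pnorm fft setNames
#' @importFrom utils read.csv write.csv
NULL

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (integer && x != round(x))
    abort_field(field, "must be an integer")
  if (x < lo || x > hi)
    abort_field(field, sprintf("must be in [%s, %s], got %s", lo, hi, x))
  invisible(x)
}

check_rgb_array <- function(x, field = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", field), call. = FALSE)
  invisible(x)
}

#' Numerically stable row-wise softmax
#' @param x numeric matrix (or vector, treated as one row)
#' @return matrix of the same shape; rows sum to 1
#' @keywords internal
softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Clip 0-255 and round to integers
#' @keywords internal
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

# Flatten a nested numeric structure to one vector (used for global grad norm)
global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}
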