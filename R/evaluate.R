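#' Evaluate state predictions against ground truth
#'
#' Top-1 accuracy per state (correct / total, in percent), their unweighted
#' average, raw and row-normalized confusion matrices (7x7, 6x6, 9x9), and
#' the adjacent-stage accuracy: the share of predictions whose class index
#' is within one of the truth. During curing, adjacent stages are visually
#' similar and a one-stage error has little practical impact, so the
#' adjacent accuracy is the operational fault-tolerance figure.
#'
#' @param predictions data.frame with integer columns `yellowing`,
#'   `browning`, `drying` (predicted class indices), e.g. the `classes`
#'   element of [predict.leafcure_model()].
#' @param truth data.frame with the same columns holding true labels.
#' @return object of class `evaluation_report`: list with `accuracy` (named
#'   per-state %, plus `average`), `adjacent_accuracy` (named per-state %),
#'   `confusion` and `confusion_normalized` (lists of matrices), `n`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  states <- c("yellowing", "browning", "drying")
  sizes <- c(yellowing = N_YELLOWING, browning = N_BROWNING,
             drying = N_DRYING)
  if (!all(states %in% names(predictions)) ||
      !all(states %in% names(truth)))
    stop("predictions and truth need yellowing/browning/drying columns",
         call. = FALSE)
  n <- nrow(predictions)
  if (is.null(n) || n == 0L || n != nrow(truth))
    stop("empty or length-mismatched predictions/truth", call. = FALSE)
  acc <- numeric(0)
  adj <- numeric(0)
  conf <- list()
  confn <- list()
  for (s in states) {
    k <- sizes[[s]]
    pr <- predictions[[s]]
    tr <- truth[[s]]
    if (any(pr < 0 | pr >= k) || any(tr < 0 | tr >= k))
      stop(sprintf("%s class index out of range 0..%d", s, k - 1L),
           call. = FALSE)
    cm <- table(factor(tr, levels = 0:(k - 1L)),
                factor(pr, levels = 0:(k - 1L)))
    cm <- matrix(as.integer(cm), k, k,
                 dimnames = list(truth = 0:(k - 1L), pred = 0:(k - 1L)))
    rs <- rowSums(cm)
    cmn <- cm / ifelse(rs == 0, 1, rs)
    acc[s] <- 100 * sum(diag(cm)) / n
    adj[s] <- 100 * mean(abs(pr - tr) <= 1L)
    conf[[s]] <- cm
    confn[[s]] <- cmn
  }
  acc["average"] <- mean(acc[states])
  structure(list(accuracy = acc, adjacent_accuracy = adj, confusion = conf,
                 confusion_normalized = confn, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report, n = %d>\n", x$n))
  cat(sprintf("  top-1 accuracy (%%):   yellowing %5.1f  browning %5.1f  drying %5.1f  average %5.1f\n",
              x$accuracy[["yellowing"]], x$accuracy[["browning"]],
              x$accuracy[["drying"]], x$accuracy[["average"]]))
  cat(sprintf("  +/-1-stage accuracy:  yellowing %5.1f  browning %5.1f  drying %5.1f\n",
              x$adjacent_accuracy[["yellowing"]],
              x$adjacent_accuracy[["browning"]],
              x$adjacent_accuracy[["drying"]]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON summary plus one CSV per raw confusion matrix.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(list(accuracy = as.list(report$accuracy),
                            adjacent_accuracy =
                              as.list(report$adjacent_accuracy),
                            n = report$n),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(report$confusion))
    write.csv(report$confusion[[s]],
              file.path(dir, sprintf("confusion_%s.csv", s)))
  invisible(dir)
}
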