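#' Hyperparameters of the classical baselines
#'
#' KNN with 5 neighbours and the Frobenius norm of the image difference as
#' the distance (equivalently, Euclidean distance between flattened pixel
#' matrices); linear SVM with C = 1; random forest with 100 trees, Gini
#' impurity, bootstrap resampling.
#'
#' @return nested list of class `baseline_config`.
#' @export
baseline_config <- function() {
  structure(list(
    knn = list(neighbors = 5L, distance = "frobenius"),
    svm = list(C = 1, kernel = "linear", penalty = "L2",
               loss = "squared_hinge"),
    rf = list(trees = 100L, criterion = "gini", bootstrap = TRUE,
              n_bins = 1024L)),
    class = "baseline_config")
}

baseline_features <- function(manifest, representation, size, model_cfg) {
  imgs <- lapply(manifest$path, load_image, size = size)
  if (representation == "pixels") {
    x <- t(vapply(imgs, function(im) as.vector(im) / 255,
                  numeric(size * size * 3)))
  } else {
    x <- t(vapply(imgs, function(im) {
      fi <- frequency_intensity(dft2(to_grayscale(im)),
                                model_cfg$cutoff_fraction)
      cv <- ccfm_input(im, model_cfg)
      c(fi$high, fi$low, cv)
    }, numeric(2 + 5 * model_cfg$k_colors)))
  }
  x
}

#' Fit a classical baseline on a labelled manifest
#'
#' One independent classifier per state. KNN consumes raw flattened pixels
#' and classifies by the Frobenius norm of the image difference; SVM and
#' random forest consume either flattened pixels or the package's
#' engineered features (frequency intensities plus the colour descriptor),
#' selected by `representation`.
#'
#' @param train_manifest,test_manifest data.frames from [read_manifest()].
#' @param which `"knn"`, `"svm"` or `"rf"`.
#' @param config a [baseline_config()].
#' @param representation `"pixels"` (default) or `"modules"`.
#' @param size side length images are resized to before flattening.
#' @param model_cfg a [leafcure_config()] supplying the engineered-feature
#'   settings when `representation = "modules"`.
#' @return object of class `baseline_fit`: list with `report`
#'   (an `evaluation_report` on the test manifest), `predictions`, `which`,
#'   `representation`.
#' @export
fit_baseline <- function(train_manifest, test_manifest,
                         which = c("knn", "svm", "rf"),
                         config = baseline_config(),
                         representation = c("pixels", "modules"),
                         size = 32L, model_cfg = leafcure_config()) {
  which <- match.arg(which)
  representation <- match.arg(representation)
  xtr <- baseline_features(train_manifest, representation, size, model_cfg)
  xte <- baseline_features(test_manifest, representation, size, model_cfg)
  states <- c("yellowing", "browning", "drying")
  preds <- list()
  for (s in states) {
    ytr <- factor(train_manifest[[s]])
    pr <- switch(which,
      knn = class::knn(xtr, xte, ytr, k = config$knn$neighbors),
      svm = {
        fit <- e1071::svm(xtr, ytr, kernel = config$svm$kernel,
                          cost = config$svm$C, scale = FALSE)
        predict(fit, xte)
      },
      rf = {
        fit <- randomForest::randomForest(xtr, ytr,
                                          ntree = config$rf$trees)
        predict(fit, xte)
      })
    preds[[s]] <- as.integer(as.character(pr))
  }
  preds <- as.data.frame(preds)
  report <- evaluate_predictions(preds, test_manifest[states])
  structure(list(report = report, predictions = preds, which = which,
                 representation = representation),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit %s (%s features)>\n", x$which,
              x$representation))
  print(x$report)
  invisible(x)
}
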