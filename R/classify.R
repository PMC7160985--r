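#' Classifier specification
#'
#' @param kind \code{"svm"} (radial-basis kernel, cost 1, kernel width
#'   1/#features) or \code{"nnet"} (one hidden layer).
#' @param hidden_nodes Hidden nodes for the neural net (default 3).
#' @param weight_decay Weight decay for the neural net (default 0.01).
#' @param max_iterations Training iteration cap for the neural net.
#' @param seed Integer seed (fold assignment and neural-net initialization).
#' @return A list of class \code{classifier_spec}.
#' @export
classifier_spec <- function(kind = c("svm", "nnet"), hidden_nodes = 3,
                            weight_decay = 0.01, max_iterations = 500,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "nnet" && hidden_nodes < 1)
    stop("hidden_nodes must be >= 1")
  structure(list(kind = kind, hidden_nodes = hidden_nodes,
                 weight_decay = weight_decay,
                 max_iterations = max_iterations, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Balanced (stratified) k-fold assignment
#'
#' Folds are stratified by class so that per-fold class counts differ from
#' the global proportions by at most one sample.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (>= 2; each class must have >= k members).
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k), aligned with
#'   \code{labels}; deterministic for a fixed seed.
#' @export
balanced_kfold <- function(labels, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2 (no held-out data otherwise)")
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k = ", k, " members; smallest has ",
         min(tab))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated group classification
#'
#' Trains the requested classifier on each training fold (features
#' standardized to zero mean and unit variance using training-fold statistics
#' only) and pools the out-of-fold predictions into one confusion matrix.
#'
#' @param features Samples x features numeric matrix (no missing values),
#'   e.g. per-sample pathway scores.
#' @param labels Binary class labels (e.g. \code{"SLC"} / \code{"CA"}).
#' @param spec A \code{\link{classifier_spec}}.
#' @param k Number of folds.
#' @return A list of class \code{confusion_matrix}: \code{counts} (given x
#'   predicted) and \code{n_total}.
#' @export
crossval_classify <- function(features, labels, spec = classifier_spec(),
                              k = 5) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must contain exactly 2 classes; got ", nlevels(labels))
  fold <- balanced_kfold(labels, k, seed = spec$seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sg <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sg, `/`)
    xte <- sweep(sweep(features[!tr, , drop = FALSE], 2, mu), 2, sg, `/`)
    if (spec$kind == "svm") {
      fit <- e1071::svm(xtr, labels[tr], kernel = "radial", cost = 1,
                        gamma = 1 / ncol(features), scale = FALSE)
      pred[!tr] <- stats::predict(fit, xte)
    } else {
      set.seed(child_seed(spec$seed, f))
      fit <- nnet::nnet(xtr, stats::model.matrix(~ labels[tr] - 1),
                        size = spec$hidden_nodes, decay = spec$weight_decay,
                        maxit = spec$max_iterations, trace = FALSE,
                        softmax = TRUE)
      pred[!tr] <- factor(levels(labels)[max.col(stats::predict(fit, xte))],
                          levels = levels(labels))
    }
  }
  counts <- table(given = labels, predicted = pred)
  structure(list(counts = unclass(counts), n_total = length(labels)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param counts 2x2 matrix of non-negative integer counts, rows = given
#'   class, columns = predicted class (matching dimnames).
#' @return A list of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts, n_total = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (given x predicted), n =", x$n_total, "\n")
  print(x$counts)
  m <- confusion_metrics(x)
  cat(sprintf("accuracy %.2f%%, misclassification %.1f%%\n",
              m$accuracy, m$misclassification))
  invisible(x)
}

#' Accuracy and misclassification rate from a confusion matrix
#'
#' Accuracy is 100 x (diagonal sum)/n; misclassification is its complement.
#' Values are returned unrounded (they sum to 100 exactly); the print method
#' shows them to two and one decimal places respectively.
#'
#' @param cm A \code{\link{confusion_matrix}}.
#' @return A list: \code{accuracy}, \code{misclassification} (percent).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_total == 0) stop("empty confusion matrix")
  acc <- 100 * sum(diag(cm$counts)) / cm$n_total
  list(accuracy = acc, misclassification = 100 - acc)
}
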