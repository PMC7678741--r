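#' Fit a two-class linear soft-margin SVM
#'
#' Trains a linear support-vector machine on a small feature block using a
#' deterministic maximal-violating-pair SMO solver on the dual problem
#' (objective: minimize 1/2 ||w||^2 + C * sum of hinge losses). Features are
#' z-scored per column before fitting (means/SDs stored in the model);
#' LFQ intensities span orders of magnitude, so standardization keeps the
#' regularization comparable across proteins. Group `"C"` is the positive
#' class; the decision function is `w . z(x) + b`, with `>= 0` predicting
#' `"C"`.
#'
#' @param features numeric samples x features matrix; no missing values.
#' @param labels group per sample, values in `{"A", "C"}` (character or
#'   factor), in row order of `features`.
#' @param cost soft-margin regularization parameter C (> 0); default 1.
#' @param tol KKT violation tolerance of the SMO solver.
#' @param max_iter iteration cap of the solver.
#' @param standardize z-score features before fitting (default TRUE).
#' @return an `svm_model`: weights and bias in standardized feature space,
#'   the stored `feature_means` / `feature_sds`, dual coefficients, and
#'   solver diagnostics.
#' @export
fit_svm <- function(features, labels, cost = 1, tol = 1e-6,
                    max_iter = 20000L, standardize = TRUE) {
  features <- as.matrix(features)
  if (!is.numeric(features) || nrow(features) < 2 || ncol(features) < 1)
    .thrombo_error("precondition", "features must be a numeric matrix with >= 2 samples and >= 1 feature")
  if (anyNA(features))
    .thrombo_error("precondition", "features must not contain missing values")
  if (!is.numeric(cost) || cost <= 0)
    .thrombo_error("config", "cost must be > 0")
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    .thrombo_error("alignment", "labels must match rows of features")
  bad <- setdiff(unique(labels), c("A", "C"))
  if (length(bad) > 0)
    .thrombo_error("format", "labels must be 'A' or 'C' (found: %s)",
                   paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2)
    .thrombo_error("precondition", "both classes must be present")

  y <- ifelse(labels == "C", 1L, -1L)
  if (standardize) {
    means <- colMeans(features)
    sds <- apply(features, 2, sd)
    zero_var <- sds <= 0 | !is.finite(sds)
    if (any(zero_var)) {
      warning(sprintf("%d zero-variance feature(s); SD set to 1 (no information after centering)",
                      sum(zero_var)))
      sds[zero_var] <- 1
    }
  } else {
    means <- rep(0, ncol(features))
    sds <- rep(1, ncol(features))
  }
  z <- sweep(sweep(features, 2, means, "-"), 2, sds, "/")

  fit <- .svm_fit_cpp(z, as.integer(y), cost, tol, as.integer(max_iter))
  structure(
    list(weights = setNames(as.numeric(fit$weights), colnames(features)),
         bias = fit$bias, regularization_c = cost,
         feature_means = setNames(as.numeric(means), colnames(features)),
         feature_sds = setNames(as.numeric(sds), colnames(features)),
         alpha = as.numeric(fit$alpha), labels = labels,
         decision = as.numeric(fit$decision),
         iterations = fit$iterations, converged = fit$converged,
         tol = tol),
    class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("linear SVM (C = %g): %d features, %d support vectors\n",
              x$regularization_c, length(x$weights),
              sum(x$alpha > 1e-8 * x$regularization_c)))
  invisible(x)
}

#' Decision values and predictions of a fitted SVM
#'
#' @param object an `svm_model` from [fit_svm()].
#' @param features samples x features matrix on the original (unstandardized)
#'   scale, columns in model order.
#' @param ... unused.
#' @return factor of predicted groups (`A`/`C`) with the numeric decision
#'   values in attribute `"decision"`.
#' @export
predict.svm_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != length(object$weights))
    .thrombo_error("precondition", "feature count does not match the model")
  z <- sweep(sweep(features, 2, object$feature_means, "-"),
             2, object$feature_sds, "/")
  dec <- as.numeric(z %*% object$weights + object$bias)
  pred <- factor(ifelse(dec >= 0, "C", "A"), levels = c("A", "C"))
  names(pred) <- rownames(features)
  attr(pred, "decision") <- setNames(dec, rownames(features))
  pred
}

#' Resubstitution (training-set) classification accuracy
#'
#' Scores a fitted SVM on the same samples it was trained on. With small
#' cohorts no honest held-out validation is possible; the resubstitution
#' accuracy is used as a descriptive discriminability measure of the feature
#' panel, not as an estimate of generalization.
#'
#' @param model an `svm_model`.
#' @param features samples x features matrix (original scale).
#' @param labels true groups (`A`/`C`) in row order.
#' @return a `classification_result`: `accuracy_percent` (full precision;
#'   printed to one decimal), `n`, `predicted_labels`, and
#'   `misclassified_ids` (list of sample IDs per true group).
#' @export
resubstitution_accuracy <- function(model, features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    .thrombo_error("alignment", "labels must match rows of features")
  pred <- predict(model, features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  wrong <- as.character(pred) != labels
  structure(
    list(accuracy_percent = 100 * mean(!wrong),
         n = length(labels),
         predicted_labels = setNames(as.character(pred), ids),
         misclassified_ids = list(
           A = ids[wrong & labels == "A"],
           C = ids[wrong & labels == "C"])),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("resubstitution accuracy: %.1f%% (%d/%d correct)\n",
              x$accuracy_percent,
              x$n - length(unlist(x$misclassified_ids)), x$n))
  if (length(unlist(x$misclassified_ids)) > 0)
    cat(sprintf("  misclassified  A: %s | C: %s\n",
                paste(x$misclassified_ids$A, collapse = ", "),
                paste(x$misclassified_ids$C, collapse = ", ")))
  invisible(x)
}

# fit + resubstitution score in one call, used by the search wrappers
.panel_score <- function(features, labels, cost = 1, tol = 1e-6,
                         max_iter = 20000L) {
  model <- suppressWarnings(fit_svm(features, labels, cost = cost, tol = tol,
                                    max_iter = max_iter))
  resubstitution_accuracy(model, features, labels)
}
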