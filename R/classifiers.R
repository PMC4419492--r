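# Soft-margin kernel SVM training and prediction. The dual quadratic program
# is solved by libsvm (through e1071); this module owns the per-class penalty
# plumbing, standardization, the kernel specification and the decision
# function, and exposes the dual coefficients for auditing.

#' Kernel specification
#'
#' @param name `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width; `NULL` selects `1 / (d * v)` at training time,
#'   where `d` is the feature dimension and `v` the mean per-feature variance
#'   of the (possibly standardized) training matrix. This default is
#'   scale-free: on z-scored features it reduces to `1 / d`.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("rbf", "linear"), gamma = NULL) {
  name <- match.arg(name)
  structure(list(name = name, gamma = gamma), class = "kernel_spec")
}

#' Derive the majority-class penalty from the class ratio
#'
#' The biased SVM keeps the minority penalty at `C_plus` and shrinks the
#' majority penalty in proportion to the imbalance:
#' `C_minus = round(C_plus / round(n_ratio))`, floored at 1. Rounding is half
#' away from zero. For `C_plus = 10` and `n_ratio = 454/75` (about 6) this
#' gives `C_minus = 2`.
#'
#' @param C_plus positive penalty on the minority (+1) class.
#' @param n_ratio majority-to-minority sample count ratio, `>= 1`.
#' @return `C_minus`, a positive number.
#' @export
biased_penalty_from_ratio <- function(C_plus, n_ratio) {
  if (n_ratio < 1) {
    abort_rusmote("n_ratio must be >= 1", "rusmote_bad_params")
  }
  max(1, round_half_up(C_plus / round_half_up(n_ratio)))
}

train_svm_impl <- function(train, C_plus, C_minus, kernel, standardize) {
  validate_labeled_dataset(train)
  cnt <- dataset_counts(train)
  if (cnt[["minority"]] == 0 || cnt[["majority"]] == 0) {
    abort_rusmote("training data must contain both classes",
                  "rusmote_empty_class")
  }
  if (C_plus <= 0 || C_minus <= 0) {
    abort_rusmote("penalties must be positive", "rusmote_bad_params")
  }
  if (!inherits(kernel, "kernel_spec")) kernel <- kernel_spec(kernel)

  x <- train$features
  std <- NULL
  if (standardize) {
    std <- fit_standardizer(x)
    x <- apply_standardizer(x, std)
  }
  gamma <- kernel$gamma
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    gamma <- 1 / (ncol(x) * v)
  }
  # factor levels fixed so libsvm's first class is +1 and positive decision
  # values always mean the minority class
  y <- factor(ifelse(train$labels > 0, "1", "-1"), levels = c("1", "-1"))
  fit <- e1071::svm(
    x, y, scale = FALSE, type = "C-classification",
    kernel = if (kernel$name == "rbf") "radial" else "linear",
    cost = C_plus, gamma = gamma, tolerance = 1e-4,
    class.weights = c("1" = 1, "-1" = C_minus / C_plus))

  structure(list(
    support_vectors = x[fit$index, , drop = FALSE],
    support_indices = fit$index,
    coefs = as.numeric(fit$coefs),      # alpha_i * y_i
    alphas = abs(as.numeric(fit$coefs)),
    offset = -fit$rho,
    kernel = kernel_spec(kernel$name, gamma),
    class_penalties = c(C_plus = C_plus, C_minus = C_minus),
    standardization = std,
    feature_names = train$feature_names
  ), class = "rusmote_svm")
}

#' Train a standard C-SVM
#'
#' Solves the dual soft-margin problem with box constraint `0 <= alpha_i <= C`
#' and classifies by the sign of
#' `f(x) = sum_i alpha_i y_i K(x, x_i) + b`.
#'
#' @param train a [labeled_dataset()] containing both classes.
#' @param C positive penalty constant.
#' @param kernel a [kernel_spec()] or kernel name.
#' @param standardize z-score features (constants fitted on `train` and
#'   reapplied at prediction time).
#' @return an object of class `rusmote_svm` exposing `support_indices`,
#'   `alphas`, `coefs` (`alpha_i * y_i`), `offset`, `kernel`,
#'   `class_penalties` and the standardization constants.
#' @export
train_csvm <- function(train, C = 10, kernel = kernel_spec("rbf"),
                       standardize = TRUE) {
  train_svm_impl(train, C, C, kernel, standardize)
}

#' Train a biased SVM with per-class penalties
#'
#' Identical to [train_csvm()] except that the box constraint is `C_plus` for
#' minority (+1) support coefficients and `C_minus` for majority (-1) ones,
#' so misclassifying a minority sample costs more when `C_plus > C_minus`.
#' With `C_plus == C_minus` the model reduces exactly to the standard C-SVM.
#'
#' @inheritParams train_csvm
#' @param C_plus,C_minus positive per-class penalties.
#' @return an object of class `rusmote_svm`.
#' @export
train_biased_svm <- function(train, C_plus = 10, C_minus = 2,
                             kernel = kernel_spec("rbf"), standardize = TRUE) {
  train_svm_impl(train, C_plus, C_minus, kernel, standardize)
}

#' @export
print.rusmote_svm <- function(x, ...) {
  cat(sprintf(
    "<rusmote_svm> %s kernel (gamma = %s), C+ = %g, C- = %g, %d SVs\n",
    x$kernel$name, format(x$kernel$gamma), x$class_penalties[["C_plus"]],
    x$class_penalties[["C_minus"]], length(x$support_indices)))
  invisible(x)
}

#' Decision values of a trained SVM
#'
#' Evaluates `f(x) = sum_i alpha_i y_i K(x, x_i) + b` directly from the stored
#' dual coefficients; positive values vote for the minority (+1) class.
#'
#' @param model an `rusmote_svm`.
#' @param X numeric matrix with the training feature dimension.
#' @return numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$support_vectors)) {
    abort_rusmote(sprintf("expected %d feature columns, got %d",
                          ncol(model$support_vectors), ncol(X)),
                  "rusmote_dim_mismatch")
  }
  if (nrow(X) == 0) return(numeric())
  if (!is.null(model$standardization)) {
    X <- apply_standardizer(X, model$standardization)
  }
  sv <- model$support_vectors
  K <- if (model$kernel$name == "rbf") {
    d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
    exp(-model$kernel$gamma * pmax(d2, 0))
  } else {
    X %*% t(sv)
  }
  as.numeric(K %*% model$coefs + model$offset)
}

#' Predict class labels
#'
#' @param object an `rusmote_svm` model.
#' @param newdata feature matrix (columns must match the training dimension).
#' @param ... unused.
#' @return vector of labels in `{+1, -1}`; a decision value of exactly 0 is
#'   mapped to `+1`.
#' @export
predict.rusmote_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  as.numeric(ifelse(f >= 0, 1, -1))
}
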