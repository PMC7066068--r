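#' Classifier and cross-validation specifications
#'
#' `classifier_spec()` describes the margin classifier used to evaluate
#' gene subsets: an SVM (via \pkg{e1071}) with a radial-basis or linear
#' kernel. Defaults mirror the back-end's own defaults — radial kernel,
#' cost 1, kernel width equal to the reciprocal of the number of features,
#' features standardized on the training fold — since those are the
#' best-evidence configuration when only the implementation is named.
#' No class weighting is applied despite imbalance; imbalance is handled
#' at the metric level by the Matthews correlation coefficient.
#'
#' `cv_scheme()` describes the cross-validation plan. `loocv` tests every
#' sample one-by-one against a model trained on the remaining N - 1;
#' `stratified_kfold` (seeded) splits each class round-robin across k folds
#' and is the scalable stand-in for LOOCV on large matrices.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost Positive soft-margin cost.
#' @param gamma Positive kernel width, or `"reciprocal_n_features"`.
#' @param standardize Standardize features using training-fold statistics.
#' @return A `classifier_spec` / `cv_scheme` list.
#' @export
classifier_spec <- function(kernel = c("rbf", "linear"), cost = 1,
                            gamma = "reciprocal_n_features",
                            standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (!is.numeric(cost) || cost <= 0) stop("cost must be > 0", call. = FALSE)
  if (is.numeric(gamma) && gamma <= 0) stop("numeric gamma must be > 0", call. = FALSE)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param kind `"loocv"` or `"stratified_kfold"`.
#' @param k Number of folds for `stratified_kfold`.
#' @param seed Integer seed for the fold shuffle.
#' @export
cv_scheme <- function(kind = c("loocv", "stratified_kfold"), k = 5L,
                      seed = 1L) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (kind == "stratified_kfold" && k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(kind = kind, k = k, seed = as.integer(seed)),
            class = "cv_scheme")
}

# Fold assignment: integer fold id per sample. LOOCV is k-fold with k = N.
make_folds <- function(y, cv) {
  n <- length(y)
  if (cv$kind == "loocv") return(seq_len(n))
  folds <- integer(n)
  rng <- local_rng(cv$seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[rng$sample(length(idx))]
    folds[idx] <- rep_len(seq_len(cv$k), length(idx))
  }
  folds
}

# Seeded RNG scoped to a closure so callers' RNG state is untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  list(
    sample = function(n) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      out <- sample.int(n)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      out
    })
}

#' Cross-validated class predictions on a gene subset
#'
#' Restricts the expression matrix to `genes`, then predicts every cell's
#' tissue label exactly once with a classifier that never saw that cell:
#' under LOOCV each cell is held out in turn; under stratified k-fold each
#' fold is held out in turn. Feature standardization (when requested) is
#' fitted on the training fold only and applied to the held-out cells.
#'
#' @param m Genes x cells expression matrix (values as fed to the
#'   classifier, e.g. after any log transform).
#' @param labels Per-cell binary labels.
#' @param genes Gene identifiers to use as features.
#' @param spec A [classifier_spec()].
#' @param cv A [cv_scheme()].
#' @param positive Name of the positive class.
#' @return Factor of predicted labels, one per cell, levels
#'   `(negative, positive)`.
#' @export
cross_validated_predictions <- function(m, labels, genes = rownames(m),
                                        spec = classifier_spec(),
                                        cv = cv_scheme("loocv"),
                                        positive = as_positive(labels)) {
  if (!length(genes)) stop("gene set must be non-empty", call. = FALSE)
  stopifnot(all(genes %in% rownames(m)))
  y <- as_binary_labels(labels, positive = positive)
  x <- t(m[genes, , drop = FALSE])   # cells x features
  folds <- make_folds(y, cv)
  gamma <- if (identical(spec$gamma, "reciprocal_n_features"))
    1 / ncol(x) else spec$gamma
  kernel <- if (spec$kernel == "rbf") "radial" else "linear"
  pred <- factor(rep(levels(y)[1L], length(y)), levels = levels(y))
  for (f in unique(folds)) {
    test <- folds == f
    ytr <- y[!test]
    if (nlevels(droplevels(ytr)) < 2L) {
      stop("a training fold lost a class entirely; use stratified_kfold ",
           "or provide more data", call. = FALSE)
    }
    fit <- suppressWarnings(e1071::svm(
      x = x[!test, , drop = FALSE], y = ytr,
      type = "C-classification", kernel = kernel,
      cost = spec$cost, gamma = gamma, scale = spec$standardize))
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  names(pred) <- colnames(m)
  pred
}

#' Confusion matrix for binary predictions
#'
#' @param predicted,actual Equal-length label vectors.
#' @param positive Name of the positive class; every label must be either
#'   `positive` or the single other class present in `actual`.
#' @return A `confusion_matrix` list with integer fields `TP`, `FP`, `TN`,
#'   `FN` (totals conserve the number of samples).
#' @examples
#' confusion(c("t","t","t","p","p"), c("t","t","t","p","p"), positive = "t")
#' @export
confusion <- function(predicted, actual, positive) {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  lv <- unique(c(actual, predicted))
  negative <- setdiff(lv, positive)
  if (length(negative) > 1L) {
    stop("labels outside {positive, negative}: found classes ",
         paste(lv, collapse = ", "), " with positive = '", positive, "'",
         call. = FALSE)
  }
  p <- predicted == positive
  a <- actual == positive
  structure(list(TP = sum(p & a), FP = sum(p & !a),
                 TN = sum(!p & !a), FN = sum(!p & a),
                 positive = positive),
            class = "confusion_matrix")
}

#' Confusion matrix from raw counts
#'
#' Convenience constructor when the four cells are already known (e.g.
#' from a published table).
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @param positive Display name of the positive class.
#' @export
confusion_counts <- function(TP, FP, TN, FN, positive = "tumor") {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 TN = as.numeric(TN), FN = as.numeric(FN),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (positive = %s)\n", x$positive))
  print(matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
               dimnames = list(c("actual +", "actual -"),
                               c("pred +", "pred -"))))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A balanced correlation measure in \[-1, 1\] that is robust to class
#' imbalance. When any factor of the denominator is zero the coefficient is
#' defined as 0 (the usual convention for the 0/0 case).
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(TP = 2220, FN = 123, FP = 181, TN = 1065))  # 0.812
#' @export
mcc <- function(cm) {
  TP <- as.numeric(cm$TP); TN <- as.numeric(cm$TN)
  FP <- as.numeric(cm$FP); FN <- as.numeric(cm$FN)
  den <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  if (any(den == 0)) return(0)
  (TP * TN - FP * FN) / sqrt(prod(den))
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / N`. A zero denominator is an error naming the
#' empty margin rather than a silent `NaN`.
#'
#' @param cm A `confusion_matrix`.
#' @export
sensitivity <- function(cm) {
  if (cm$TP + cm$FN == 0) stop("no actual positives (TP + FN = 0)", call. = FALSE)
  cm$TP / (cm$TP + cm$FN)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  if (cm$TN + cm$FP == 0) stop("no actual negatives (TN + FP = 0)", call. = FALSE)
  cm$TN / (cm$TN + cm$FP)
}

#' @rdname sensitivity
#' @export
accuracy <- function(cm) {
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  (cm$TP + cm$TN) / n
}
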