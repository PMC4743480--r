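#' Confusion matrix for binary predictions
#'
#' @param predictions,truths Equal-length label vectors.
#' @param positive The positive class label.
#' @return Object of class `confusion_matrix`: named integer vector with
#'   elements `TP`, `FP`, `FN`, `TN` (their sum is the number of rows).
#' @export
confusion <- function(predictions, truths, positive) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths)) {
    stop("confusion: predictions and truths differ in length")
  }
  classes <- unique(c(truths, positive))
  if (length(classes) > 2) {
    stop("confusion: more than two classes present: ",
         paste(classes, collapse = ", "))
  }
  unknown <- setdiff(unique(predictions), classes)
  if (length(unknown)) {
    stop("confusion: unknown predicted label(s): ",
         paste(unknown, collapse = ", "))
  }
  p <- predictions == positive
  t <- truths == positive
  structure(c(TP = sum(p & t), FP = sum(p & !t),
              FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_matrix", positive = positive)
}

#' The four classification statistics
#'
#' Computes accuracy, sensitivity and specificity as percentages and the
#' Matthews correlation coefficient from a confusion matrix:
#' \deqn{Acc = 100 (TP+TN)/N,\quad Sens = 100\, TP/(TP+FN),}
#' \deqn{Spec = 100\, TN/(TN+FP),}
#' \deqn{MCC = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' A zero factor in the MCC denominator yields MCC = 0. A zero
#' sensitivity/specificity denominator yields `NA` with a warning.
#'
#' @param cm A `confusion_matrix` from [confusion()], or a named vector
#'   with elements TP, FP, FN, TN.
#' @return Object of class `metrics_report`: named numeric vector
#'   `accuracy`, `sensitivity`, `specificity` (percent) and `mcc`.
#' @export
metrics <- function(cm) {
  cm <- cm[c("TP", "FP", "FN", "TN")]
  if (anyNA(cm) || any(cm < 0)) stop("metrics: invalid confusion matrix")
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  fn <- as.numeric(cm[["FN"]]); tn <- as.numeric(cm[["TN"]])
  n <- tp + fp + fn + tn
  if (n == 0) stop("metrics: empty confusion matrix")
  sens <- if (tp + fn == 0) {
    warning("metrics: no positive rows; sensitivity undefined")
    NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("metrics: no negative rows; specificity undefined")
    NA_real_
  } else 100 * tn / (tn + fp)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(c(accuracy = 100 * (tp + tn) / n, sensitivity = sens,
              specificity = spec, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("accuracy %.3f %%  sensitivity %.3f %%  specificity %.3f %%  MCC %.3f\n",
              v[["accuracy"]], v[["sensitivity"]], v[["specificity"]],
              v[["mcc"]]))
  invisible(x)
}

#' PCA-stratified random train/test split
#'
#' Within each class the features are z-scored, projected onto the first
#' principal component, and PC1 is binned into up to 10 equal-frequency
#' strata; the test fraction is then sampled uniformly within each stratum.
#' This keeps both tails and the bulk of each class represented in the
#' external test set while preserving exact split sizes: per class,
#' `|train| = floor(train_fraction * n + 0.5)`.
#'
#' @param ft A [feature_table()] with at least 7 rows per class (smaller
#'   classes fall back to a plain seeded random split, with a warning).
#' @param train_fraction Fraction of rows assigned to training (default
#'   0.85).
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids`, `seed`,
#'   `method` ("pca_stratified" or "plain_random" per class).
#' @export
pca_random_split <- function(ft, train_fraction = 0.85, seed) {
  stopifnot(inherits(ft, "feature_table"),
            train_fraction > 0, train_fraction < 1)
  if (missing(seed)) stop("pca_random_split: seed is required")
  train_ids <- character(0); test_ids <- character(0)
  method <- character(0)
  rng <- local_rng(seed)
  for (cl in levels(ft$labels)) {
    idx <- which(ft$labels == cl)
    n <- length(idx)
    n_train <- floor(train_fraction * n + 0.5)
    n_test <- n - n_train
    if (n < 7) {
      warning("pca_random_split: class '", cl,
              "' too small to stratify; plain random split used")
      test <- rng$sample(idx, n_test)
      method <- c(method, stats::setNames("plain_random", cl))
    } else {
      z <- scale_features(ft$x[idx, , drop = FALSE])
      pc1 <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
      n_strata <- min(10L, n)
      breaks <- unique(stats::quantile(pc1, probs = seq(0, 1,
                                                        length.out = n_strata + 1)))
      stratum <- cut(pc1, breaks = breaks, include.lowest = TRUE,
                     labels = FALSE)
      # allocate test counts across strata by largest remainder
      sizes <- as.integer(table(factor(stratum, levels = seq_along(breaks))))
      sizes <- sizes[sizes > 0]
      strata_ids <- sort(unique(stratum))
      quota <- n_test * sizes / n
      take <- floor(quota)
      rem <- n_test - sum(take)
      if (rem > 0) {
        ord <- order(quota - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
      }
      test <- integer(0)
      for (s in seq_along(strata_ids)) {
        pool <- idx[stratum == strata_ids[s]]
        test <- c(test, rng$sample(pool, min(take[s], length(pool))))
      }
      # top up/trim in case of stratum collisions
      short <- n_test - length(test)
      if (short > 0) {
        test <- c(test, rng$sample(setdiff(idx, test), short))
      } else if (short < 0) {
        test <- test[seq_len(n_test)]
      }
      method <- c(method, stats::setNames("pca_stratified", cl))
    }
    test_ids <- c(test_ids, ft$ids[test])
    train_ids <- c(train_ids, ft$ids[setdiff(idx, test)])
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 seed = seed, method = method),
            class = "split_plan")
}

#' Stratified k-fold cross-validation with pooled confusion matrix
#'
#' Folds are stratified by class from the given seed; each row is predicted
#' exactly once by a model trained on the other folds, predictions are
#' pooled into a single confusion matrix and [metrics()] is applied to it
#' (pooled aggregation, not per-fold averaging).
#'
#' @param ft A [feature_table()].
#' @param learner A [learner_config()].
#' @param k Number of folds (default 10); `k = nrow` gives leave-one-out.
#' @param seed Integer seed for fold assignment (and the learner).
#' @return A `metrics_report` with attributes `confusion` (the pooled
#'   `confusion_matrix`) and `folds` (fold index per row).
#' @export
kfold_cv <- function(ft, learner, k = 10, seed) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft$x)
  if (n < k) stop("kfold_cv: fewer rows than folds")
  if (missing(seed)) stop("kfold_cv: seed is required")
  folds <- stratified_folds(ft$labels, k, seed)
  if (min(table(ft$labels)) < 2 && length(levels(ft$labels)) > 1) {
    warning("kfold_cv: a class has a single member; ",
            "its training folds cannot all contain it")
  }
  preds <- character(n)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(te) == 0) next
    model <- train_learner(ft_rows(ft, tr), learner,
                           seed = seed + f)
    preds[te] <- predict_learner(model, ft$x[te, , drop = FALSE])
  }
  cm <- confusion(preds, as.character(ft$labels), ft$positive)
  out <- metrics(cm)
  attr(out, "confusion") <- cm
  attr(out, "folds") <- folds
  out
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, k, seed) {
  rng <- local_rng(seed)
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in levels(factor(labels))) {
    idx <- which(labels == cl)
    idx <- rng$sample(idx, length(idx))
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx) %% k
  }
  folds
}
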