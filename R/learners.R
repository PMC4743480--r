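#' Learner configuration
#'
#' A common train/predict contract over the three model families. The
#' hyperparameter grid is searched by stratified 10-fold cross-validated
#' MCC on the training table (the parameter-optimization loop); a
#' single-row grid is used as-is.
#'
#' Default grids:
#' \itemize{
#'   \item `tree`: `min_leaf = 2`, `confidence = 0.25` (single point).
#'   \item `mlp`: one hidden layer, sizes `{round((p + 2) / 2), p}` for `p`
#'     features, weight decay `{0.3, 0.1}`, 500 epochs.
#'   \item `svm`: RBF kernel with `cost` in `{0.1, 1, 10, 100}` and `gamma`
#'     in `{0.01, 0.1, 1}`, plus a linear kernel over the same costs.
#' }
#'
#' @param algorithm One of `"tree"`, `"mlp"`, `"svm"`.
#' @param grid data.frame of hyperparameter rows, or `NULL` for the
#'   default grid (resolved at training time from the table dimensions).
#' @param seed Integer seed used for grid-search folds and stochastic
#'   fitting.
#' @param standardize Z-score features before fitting (default: TRUE for
#'   mlp/svm, FALSE for the tree, whose splits are scale-invariant).
#' @return Object of class `learner_config`.
#' @export
learner_config <- function(algorithm = c("tree", "mlp", "svm"),
                           grid = NULL, seed = 1,
                           standardize = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is.null(grid)) {
    grid <- as.data.frame(grid)
    if (nrow(grid) == 0) stop("learner_config: empty hyperparameter grid")
  }
  if (is.null(standardize)) standardize <- algorithm != "tree"
  structure(list(algorithm = algorithm, grid = grid, seed = seed,
                 standardize = standardize),
            class = "learner_config")
}

default_grid <- function(algorithm, p, n_classes = 2) {
  switch(algorithm,
         tree = data.frame(min_leaf = 2, confidence = 0.25),
         mlp = expand.grid(size = unique(c(round((p + n_classes) / 2), p)),
                           decay = c(0.3, 0.1), maxit = 500),
         svm = rbind(expand.grid(kernel = "radial",
                                 cost = c(0.1, 1, 10, 100),
                                 gamma = c(0.01, 0.1, 1),
                                 stringsAsFactors = FALSE),
                     expand.grid(kernel = "linear",
                                 cost = c(0.1, 1, 10, 100), gamma = NA,
                                 stringsAsFactors = FALSE)))
}

#' Train a learner under the common contract
#'
#' Resolves the hyperparameter grid (choosing the row with the highest
#' stratified 10-fold cross-validated MCC when the grid has several rows),
#' fits the final model on the full table and returns it with the chosen
#' hyperparameters recorded.
#'
#' @param ft A [feature_table()].
#' @param config A [learner_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Object of class `cspr_model`: list with `algorithm`, `fit`,
#'   `chosen` (hyperparameter row), `center`/`scale` (when standardized),
#'   `classes`, `positive`.
#' @export
train_learner <- function(ft, config, seed = NULL) {
  stopifnot(inherits(ft, "feature_table"), inherits(config, "learner_config"))
  if (is.null(seed)) seed <- config$seed
  grid <- config$grid
  if (is.null(grid)) {
    grid <- default_grid(config$algorithm, ncol(ft$x),
                         nlevels(droplevels(ft$labels)))
  }
  if (nrow(grid) > 1) {
    k <- min(10, nrow(ft$x))
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      cfg <- learner_config(config$algorithm, grid[g, , drop = FALSE],
                            seed = seed, standardize = config$standardize)
      rep <- tryCatch(suppressWarnings(kfold_cv(ft, cfg, k = k, seed = seed)),
                      error = function(e) NULL)
      if (is.null(rep)) -Inf else unname(rep[["mcc"]])
    }, numeric(1))
    grid <- grid[which.max(scores), , drop = FALSE]
  }
  fit_learner(ft, config$algorithm, grid, seed, config$standardize)
}

fit_learner <- function(ft, algorithm, params, seed, standardize) {
  x <- ft$x
  center <- scale <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    x <- scale_features(x, center, scale)
  }
  y <- droplevels(ft$labels)
  fit <- switch(
    algorithm,
    tree = train_decision_tree(
      feature_table(x, y, ids = ft$ids, positive = ft$positive),
      min_leaf = params$min_leaf, confidence = params$confidence),
    mlp = with_seed(seed, function() {
      nnet::nnet(x, stats::model.matrix(~ y - 1), size = params$size,
                 decay = params$decay, maxit = params$maxit,
                 trace = FALSE, softmax = nlevels(y) > 1)
    }),
    svm = with_seed(seed, function() {
      if (identical(as.character(params$kernel), "linear")) {
        e1071::svm(x, y, kernel = "linear", cost = params$cost,
                   scale = FALSE)
      } else {
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma, scale = FALSE)
      }
    }))
  structure(list(algorithm = algorithm, fit = fit, chosen = params,
                 center = center, scale = scale, classes = levels(y),
                 positive = ft$positive),
            class = "cspr_model")
}

#' Predict with a trained learner
#'
#' @param model A `cspr_model` from [train_learner()].
#' @param newx Numeric matrix or data.frame of features.
#' @return Character vector of predicted labels.
#' @export
predict_learner <- function(model, newx) {
  stopifnot(inherits(model, "cspr_model"))
  newx <- as.matrix(newx)
  if (!is.null(model$center)) {
    newx <- scale_features(newx[, names(model$center), drop = FALSE],
                           model$center, model$scale)
  }
  switch(model$algorithm,
         tree = predict(model$fit, newx),
         mlp = {
           pr <- predict(model$fit, newx)
           model$classes[max.col(pr, ties.method = "first")]
         },
         svm = as.character(predict(model$fit, newx)))
}

#' Train the multilayer perceptron / support-vector learners
#'
#' Thin named wrappers over [train_learner()] matching the pipeline's
#' model-family vocabulary.
#'
#' @inheritParams train_learner
#' @param grid Optional hyperparameter grid (see [learner_config()]).
#' @return A `cspr_model`.
#' @export
train_mlp <- function(ft, grid = NULL, seed = 1) {
  train_learner(ft, learner_config("mlp", grid, seed = seed))
}

#' @rdname train_mlp
#' @export
train_svm <- function(ft, grid = NULL, seed = 1) {
  train_learner(ft, learner_config("svm", grid, seed = seed))
}

#' Serialize a model to JSON
#'
#' Trees serialize as nested nodes; other learners as their algorithm and
#' chosen hyperparameters plus a parameters blob.
#'
#' @param model A `cspr_model` or `cspr_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "cspr_tree")) {
    list(algorithm = "tree", root = model$root, classes = model$classes,
         meta = model$meta)
  } else if (identical(model$algorithm, "tree")) {
    list(algorithm = "tree", root = model$fit$root,
         classes = model$classes, chosen = as.list(model$chosen))
  } else {
    list(algorithm = model$algorithm, chosen = as.list(model$chosen),
         classes = model$classes,
         parameters = list(blob = utils::capture.output(utils::str(model$fit))))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
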