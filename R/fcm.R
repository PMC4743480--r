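#' Fuzzy C-means configuration
#'
#' @param k Number of clusters (`NULL` to derive from the class ratio via
#'   [choose_cluster_count()]).
#' @param m Fuzzifier exponent (> 1; default 2). As `m` approaches 1 the
#'   memberships approach crisp k-means assignments; larger `m` gives
#'   softer memberships.
#' @param tol Convergence tolerance on the change of the objective
#'   (default 1e-6).
#' @param max_iter Iteration cap per restart (default 300).
#' @param restarts Random restarts; the run with the lowest final
#'   objective is kept (default 5).
#' @param seed Integer seed for membership initialization.
#' @return Object of class `fcm_config`.
#' @export
fcm_config <- function(k = NULL, m = 2, tol = 1e-6, max_iter = 300,
                       restarts = 5, seed = 1) {
  stopifnot(m > 1, tol > 0, max_iter >= 1, restarts >= 1)
  if (!is.null(k)) stopifnot(k >= 1)
  structure(list(k = k, m = m, tol = tol, max_iter = max_iter,
                 restarts = restarts, seed = seed), class = "fcm_config")
}

#' Fuzzy C-means clustering
#'
#' Minimizes the membership-weighted squared-distance objective
#' \deqn{J = \sum_{i=1}^{k}\sum_{j=1}^{n} u_{ij}^m \, d_{ij}^2}
#' by alternating the update rules
#' \deqn{u_{ij} = 1 / \sum_{c} (d_{ij}/d_{cj})^{2/(m-1)}, \qquad
#'       v_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m,}
#' with Euclidean distances, until the objective changes by less than
#' `tol` or `max_iter` is reached. A point coincident with one or more
#' centers receives membership split over exactly those centers (the limit
#' convention). Initialization is a random membership matrix drawn from
#' the configured seed; the best of `restarts` runs (lowest final
#' objective) is returned.
#'
#' @param x Numeric matrix (n rows, d features). Standardize features
#'   before clustering; [select_representative_cluster()] does this for
#'   you.
#' @param config An [fcm_config()] with non-`NULL` `k <= n`.
#' @return Object of class `fcm_result`: `centers` (k x d), `membership`
#'   (n x k, rows summing to 1), `objective_trajectory` (non-increasing),
#'   `assignment` (crisp argmax cluster per row), `iterations`.
#' @export
fcm_cluster <- function(x, config = fcm_config(k = 2)) {
  stopifnot(inherits(config, "fcm_config"))
  x <- as.matrix(x)
  k <- config$k
  if (is.null(k)) stop("fcm_cluster: config$k must be set")
  n <- nrow(x)
  if (n < k) stop("fcm_cluster: fewer points than clusters")
  rng <- local_rng(config$seed)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    u <- matrix(rng$runif(n * k, min = 1e-3), n, k)
    u <- u / rowSums(u)
    traj <- numeric(0)
    j_old <- Inf
    for (it in seq_len(config$max_iter)) {
      um <- u^config$m
      centers <- crossprod(um, x) / colSums(um)
      d2 <- sq_dist(x, centers)
      u <- fcm_membership(d2, config$m)
      j_new <- sum(u^config$m * d2)
      traj <- c(traj, j_new)
      if (abs(j_old - j_new) < config$tol) break
      j_old <- j_new
    }
    if (is.null(best) || j_new < best$objective_trajectory[length(best$objective_trajectory)]) {
      best <- list(centers = centers, membership = u,
                   objective_trajectory = traj,
                   assignment = max.col(u, ties.method = "first"),
                   iterations = length(traj))
    }
  }
  structure(c(best, list(m = config$m, k = k)), class = "fcm_result")
}

# n x k squared Euclidean distances
sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# membership update, with the zero-distance limit convention
fcm_membership <- function(d2, m) {
  n <- nrow(d2); k <- ncol(d2)
  pow <- d2^(-1 / (m - 1))          # u_ij proportional to d_ij^(-2/(m-1))
  zero <- d2 < .Machine$double.eps
  u <- matrix(0, n, k)
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    p <- pow[!has_zero, , drop = FALSE]
    u[!has_zero, ] <- p / rowSums(p)
  }
  u
}

#' @export
print.fcm_result <- function(x, ...) {
  cat("fcm_result: k =", x$k, ", m =", x$m, ",", x$iterations,
      "iterations, final J =",
      format(x$objective_trajectory[length(x$objective_trajectory)]), "\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Cluster count from the class ratio
#'
#' The number of majority-class clusters is derived from the ratio of
#' positive to negative class sizes: `k = max(2, ceiling(n_pos / n_neg))`,
#' so each cluster is comparable in size to the negative class.
#'
#' @param n_pos,n_neg Class sizes with `n_pos >= n_neg >= 1`.
#' @return Integer cluster count.
#' @examples
#' choose_cluster_count(197, 26)   # 8
#' choose_cluster_count(1341, 913) # 2
#' @export
choose_cluster_count <- function(n_pos, n_neg) {
  stopifnot(n_neg >= 1)
  if (n_pos < n_neg) {
    stop("choose_cluster_count: positives do not outnumber negatives; ",
         "balancing is not needed")
  }
  max(2L, as.integer(ceiling(n_pos / n_neg)))
}

#' Balance an imbalanced dataset by FCM cluster selection
#'
#' The positive (majority) class is split into `k` fuzzy clusters on
#' z-scored features; for each crisp cluster a decision tree is trained on
#' the cluster together with all negatives and scored by stratified
#' 10-fold cross-validation (leave-one-out when the cluster has fewer than
#' 10 members); the cluster with the highest MCC — ties broken by higher
#' accuracy, then larger cluster, then lower cluster id — becomes the
#' representative positive set. The balanced table is that cluster plus
#' all negatives.
#'
#' @param positives,negatives [feature_table()] objects with identical
#'   feature columns; positives must outnumber negatives.
#' @param config An [fcm_config()]; a `NULL` `k` is derived via
#'   [choose_cluster_count()].
#' @return Object of class `cluster_selection`: list with `evaluations`
#'   (data.frame: cluster_id, size, accuracy, sensitivity, specificity,
#'   mcc, cv (\"10-fold\" or \"loo\"), selected), `balanced`
#'   (a `feature_table`), `fcm` (the `fcm_result`), `selected_id`,
#'   `selected_ids` (row ids of the selected cluster).
#' @export
select_representative_cluster <- function(positives, negatives,
                                          config = fcm_config()) {
  stopifnot(inherits(positives, "feature_table"),
            inherits(negatives, "feature_table"))
  n_pos <- nrow(positives$x); n_neg <- nrow(negatives$x)
  if (n_pos <= n_neg) {
    stop("select_representative_cluster: positives must outnumber negatives")
  }
  if (is.null(config$k)) config$k <- choose_cluster_count(n_pos, n_neg)
  z <- scale_features(positives$x)
  fcm <- fcm_cluster(z, config)
  pos_label <- as.character(positives$labels[1])
  evals <- data.frame()
  for (cl in seq_len(config$k)) {
    members <- which(fcm$assignment == cl)
    if (length(members) == 0) {
      evals <- rbind(evals, data.frame(
        cluster_id = cl, size = 0, accuracy = NA, sensitivity = NA,
        specificity = NA, mcc = -Inf, cv = "none", selected = FALSE))
      next
    }
    tab <- ft_bind(ft_rows(positives, members), negatives,
                   positive = pos_label)
    loo <- length(members) < 10
    k_cv <- if (loo) nrow(tab$x) else 10
    rep <- suppressWarnings(
      kfold_cv(tab, learner_config("tree", seed = config$seed),
               k = k_cv, seed = config$seed))
    evals <- rbind(evals, data.frame(
      cluster_id = cl, size = length(members),
      accuracy = unname(rep[["accuracy"]]),
      sensitivity = unname(rep[["sensitivity"]]),
      specificity = unname(rep[["specificity"]]),
      mcc = unname(rep[["mcc"]]),
      cv = if (loo) "loo" else "10-fold", selected = FALSE))
  }
  ord <- order(-evals$mcc, -evals$accuracy, -evals$size, evals$cluster_id)
  sel <- evals$cluster_id[ord[1]]
  evals$selected <- evals$cluster_id == sel
  members <- which(fcm$assignment == sel)
  balanced <- ft_bind(ft_rows(positives, members), negatives,
                      positive = pos_label)
  structure(list(evaluations = evals, balanced = balanced, fcm = fcm,
                 selected_id = sel,
                 selected_ids = positives$ids[members]),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("cluster_selection: cluster", x$selected_id, "selected (",
      sum(x$evaluations$selected * x$evaluations$size), "positives kept)\n")
  print(x$evaluations, row.names = FALSE)
  invisible(x)
}
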