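#' Pearson intercorrelation matrix of a feature table
#'
#' @param ft A [feature_table()] (or plain numeric matrix) with at least 3
#'   rows and no missing values.
#' @return Symmetric matrix of Pearson correlation coefficients with unit
#'   diagonal. Correlations involving a constant column are defined as 0
#'   (with a warning); the diagonal stays 1.
#' @export
pearson_matrix <- function(ft) {
  x <- if (inherits(ft, "feature_table")) ft$x else as.matrix(ft)
  if (nrow(x) < 3) stop("pearson_matrix: need at least 3 rows")
  if (anyNA(x)) stop("pearson_matrix: missing values are not allowed")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning("pearson_matrix: constant column(s) ",
            paste(colnames(x)[const], collapse = ", "),
            "; their correlations are defined as 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Remove collinear features at a correlation cutoff
#'
#' Greedy left-to-right scan over the columns of the correlation matrix:
#' each surviving column eliminates every later column whose absolute
#' Pearson correlation with it reaches the cutoff. The cutoff applies to
#' |r|, so strongly anti-correlated features are treated as redundant too.
#'
#' @param r Correlation matrix from [pearson_matrix()].
#' @param cutoff Threshold on |r| (default 0.7).
#' @return A `selection_report`: list with `kept` (feature names),
#'   `removed` (data.frame `feature`, `partner`, `r` — the surviving
#'   partner that eliminated it and their correlation) and `cutoff`.
#' @export
prune_collinear <- function(r, cutoff = 0.7) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (is.null(colnames(r))) colnames(r) <- rownames(r) <-
      paste0("f", seq_len(ncol(r)))
  if (max(abs(r[row(r) != col(r)]), 0) > 1 + 1e-8 ||
      any(abs(diag(r) - 1) > 1e-8)) {
    stop("prune_collinear: not a valid correlation matrix")
  }
  nm <- colnames(r)
  alive <- rep(TRUE, length(nm))
  removed <- data.frame(feature = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_along(nm)) {
    if (!alive[i]) next
    later <- which(alive & seq_along(nm) > i & abs(r[i, ]) >= cutoff)
    for (j in later) {
      alive[j] <- FALSE
      removed <- rbind(removed, data.frame(
        feature = nm[j], partner = nm[i], r = r[i, j],
        stringsAsFactors = FALSE))
    }
  }
  structure(list(kept = nm[alive], removed = removed, cutoff = cutoff),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report: cutoff |r| >=", x$cutoff, "\n")
  cat("kept (", length(x$kept), "): ", paste(x$kept, collapse = ", "),
      "\n", sep = "")
  if (nrow(x$removed)) {
    cat("removed:\n")
    print(x$removed, row.names = FALSE)
  } else cat("removed: none\n")
  invisible(x)
}

#' Run feature selection on a table and return the pruned table
#'
#' Convenience wrapper: [pearson_matrix()] then [prune_collinear()], then
#' restriction of the table to the kept features.
#'
#' @inheritParams pearson_matrix
#' @inheritParams prune_collinear
#' @return List with `table` (pruned [feature_table()]), `report`
#'   (`selection_report`) and `correlation` (the matrix).
#' @export
select_features <- function(ft, cutoff = 0.7) {
  r <- pearson_matrix(ft)
  rep <- prune_collinear(r, cutoff)
  list(table = ft_select(ft, rep$kept), report = rep, correlation = r)
}
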