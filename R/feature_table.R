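#' Construct a feature table
#'
#' The central container of the pipeline: a numeric descriptor matrix with
#' row identifiers and a class label per row. Every stage (feature
#' selection, balancing, model building, validation) consumes and produces
#' this shape.
#'
#' @param x Numeric matrix (rows = compounds, columns = descriptors) with
#'   unique column names.
#' @param labels Character or factor of class labels, one per row.
#' @param ids Character vector of row identifiers; defaults to rownames of
#'   `x` or `"r1"`, `"r2"`, ...
#' @param positive Label of the positive class. Defaults to the first level
#'   of `factor(labels)`.
#' @return An object of class `feature_table`: a list with elements `x`
#'   (numeric matrix), `labels` (factor), `ids` (character) and `positive`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("a", "b"))),
#'                     labels = rep(c("pos", "neg"), 5), positive = "pos")
#' dim(ft)
#' @export
feature_table <- function(x, labels, ids = NULL, positive = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  if (anyDuplicated(colnames(x))) {
    stop("feature_table: column names must be unique")
  }
  if (anyNA(x)) {
    stop("feature_table: missing values are not allowed")
  }
  if (length(labels) != nrow(x)) {
    stop("feature_table: one label per row required")
  }
  if (is.null(ids)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("r", seq_len(nrow(x)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(x)) {
    stop("feature_table: one id per row required")
  }
  labels <- factor(labels)
  if (is.null(positive)) {
    positive <- levels(labels)[1]
  } else if (!positive %in% levels(labels) && nrow(x) > 0) {
    stop("feature_table: positive class '", positive, "' not among labels")
  }
  rownames(x) <- NULL
  structure(list(x = x, labels = labels, ids = ids,
                 positive = as.character(positive)),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$x), "rows x", ncol(x$x), "features\n")
  cat("features:", paste(colnames(x$x), collapse = ", "), "\n")
  tab <- table(x$labels)
  cat("classes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      " (positive = ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(id = x$ids, label = as.character(x$labels), x$x,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Subset the rows of a feature table
#'
#' @param ft A `feature_table`.
#' @param i Row index (logical, integer or id character vector).
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(ft, i) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.character(i)) i <- match(i, ft$ids)
  feature_table(ft$x[i, , drop = FALSE], droplevels(ft$labels[i]),
                ids = ft$ids[i],
                positive = if (ft$positive %in% as.character(ft$labels[i]))
                  ft$positive else NULL)
}

#' Keep only the named feature columns
#'
#' @param ft A `feature_table`.
#' @param keep Character vector of column names to retain.
#' @return A `feature_table` restricted to `keep`.
#' @export
ft_select <- function(ft, keep) {
  stopifnot(inherits(ft, "feature_table"))
  missing <- setdiff(keep, colnames(ft$x))
  if (length(missing)) {
    stop("ft_select: unknown features: ", paste(missing, collapse = ", "))
  }
  feature_table(ft$x[, keep, drop = FALSE], ft$labels, ids = ft$ids,
                positive = ft$positive)
}

#' Stack two feature tables with identical columns
#'
#' @param a,b `feature_table` objects sharing the same feature columns.
#' @param positive Positive class of the result; defaults to `a$positive`.
#' @return The row-bound `feature_table`.
#' @export
ft_bind <- function(a, b, positive = a$positive) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!identical(colnames(a$x), colnames(b$x))) {
    stop("ft_bind: feature columns differ")
  }
  feature_table(rbind(a$x, b$x),
                c(as.character(a$labels), as.character(b$labels)),
                ids = c(a$ids, b$ids), positive = positive)
}

#' Write / read a feature table as CSV
#'
#' The CSV schema is `id,label,<feature columns...>`, the same schema the
#' descriptor stage emits.
#'
#' @param ft A `feature_table`.
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @param positive Positive class label passed to [feature_table()] on read.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, positive = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("read_feature_table: CSV must have 'id' and 'label' columns")
  }
  feat <- setdiff(names(df), c("id", "label"))
  feature_table(as.matrix(df[feat]), df$label, ids = df$id,
                positive = positive)
}

# z-score columns; constant columns map to 0 (sd fallback 1)
scale_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}
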