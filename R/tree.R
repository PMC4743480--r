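#' Train a gain-ratio decision tree
#'
#' Binary-split decision tree for numeric features in the C4.5 family:
#' candidate thresholds are the midpoints between adjacent distinct sorted
#' values of a feature where the class composition changes, splits are
#' scored by information gain ratio (information gain divided by the split
#' information), growth stops at node purity or when a child would fall
#' below `min_leaf` rows, and the grown tree is simplified by
#' pessimistic-error pruning at the given confidence. Ties between splits
#' are broken toward the lower column index, then the lower threshold.
#' Rows with feature value equal to the threshold go left
#' (`<=` branches left, `>` branches right).
#'
#' @param ft A [feature_table()] with at least 2 rows. A single-class table
#'   yields a single-leaf tree.
#' @param min_leaf Minimum rows in each child of a split (default 2).
#' @param confidence Pruning confidence for the pessimistic upper error
#'   bound (default 0.25, the customary C4.5 setting).
#' @param prune Logical; apply pessimistic-error pruning (default TRUE).
#' @return Object of class `cspr_tree`: list with `root` (nested nodes),
#'   `classes`, `positive` and `meta` (n_rows, features_used,
#'   pruning_confidence, min_leaf).
#' @export
train_decision_tree <- function(ft, min_leaf = 2, confidence = 0.25,
                                prune = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  x <- ft$x
  y <- droplevels(ft$labels)
  if (nrow(x) < 1) stop("train_decision_tree: empty table")
  if (!is.numeric(x)) stop("train_decision_tree: non-numeric features")
  root <- grow_node(x, y, min_leaf)
  if (prune) root <- prune_node(root, confidence)
  structure(list(root = root, classes = levels(y), positive = ft$positive,
                 meta = list(n_rows = nrow(x),
                             features_used = tree_features(root),
                             pruning_confidence = if (prune) confidence else NA,
                             min_leaf = min_leaf)),
            class = "cspr_tree")
}

# entropy (bits) of rows of a count matrix
entropy_rows <- function(m) {
  n <- rowSums(m)
  p <- m / ifelse(n == 0, 1, n)
  plog <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(plog)
}

# Best gain-ratio split over all features.
# Returns NULL or list(feature=j, threshold, gain_ratio).
best_split <- function(x, y, min_leaf) {
  n <- nrow(x)
  ncl <- nlevels(y)
  yi <- as.integer(y)
  parent_cnt <- tabulate(yi, nbins = ncl)
  h_parent <- entropy_rows(matrix(parent_cnt, 1))
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    ys <- yi[ord]
    bnd <- which(xs[-n] < xs[-1])          # last index of each value group
    if (!length(bnd)) next
    cum <- vapply(seq_len(ncl), function(cl) cumsum(ys == cl), numeric(n))
    cum <- matrix(cum, ncol = ncl)
    # class counts per distinct-value group
    gend <- c(bnd, n)
    gcnt <- cum[gend, , drop = FALSE] -
      rbind(0, cum[gend[-length(gend)], , drop = FALSE])
    # composition-change filter between group g and g+1
    gmax <- max.col(gcnt, ties.method = "first")
    gpure <- rowSums(gcnt > 0) == 1
    ng <- nrow(gcnt)
    keep <- !(gpure[-ng] & gpure[-1] & gmax[-ng] == gmax[-1])
    bnd <- bnd[keep]
    if (!length(bnd)) next
    nl <- bnd
    nr <- n - nl
    ok <- nl >= min_leaf & nr >= min_leaf
    bnd <- bnd[ok]
    if (!length(bnd)) next
    nl <- nl[ok]; nr <- nr[ok]
    left_cnt <- cum[bnd, , drop = FALSE]
    right_cnt <- matrix(parent_cnt, length(bnd), ncl, byrow = TRUE) - left_cnt
    gain <- h_parent - (nl * entropy_rows(left_cnt) +
                          nr * entropy_rows(right_cnt)) / n
    splitinfo <- entropy_rows(cbind(nl, nr))
    gr <- ifelse(splitinfo > 0, pmax(gain, 0) / splitinfo, -Inf)
    b <- which.max(gr)                     # first max = lowest threshold
    if (is.finite(gr[b]) &&
        (is.null(best) || gr[b] > best$gain_ratio + 1e-10)) {
      best <- list(feature = j,
                   threshold = (xs[bnd[b]] + xs[bnd[b] + 1]) / 2,
                   gain_ratio = gr[b])
    }
  }
  best
}

grow_node <- function(x, y, min_leaf) {
  cnt <- tabulate(as.integer(y), nbins = nlevels(y))
  names(cnt) <- levels(y)
  leaf <- function() {
    list(type = "leaf",
         class = levels(y)[which.max(cnt)], counts = cnt)
  }
  if (sum(cnt > 0) <= 1 || nrow(x) < 2 * min_leaf) return(leaf())
  sp <- best_split(x, y, min_leaf)
  if (is.null(sp)) return(leaf())
  go_left <- x[, sp$feature] <= sp$threshold
  list(type = "split",
       feature = colnames(x)[sp$feature],
       threshold = sp$threshold,
       counts = cnt,
       left = grow_node(x[go_left, , drop = FALSE], y[go_left], min_leaf),
       right = grow_node(x[!go_left, , drop = FALSE], y[!go_left], min_leaf))
}

# C4.5 pessimistic upper bound on the error rate of a leaf with E errors
# out of N, at confidence cf. U(0, N) = 1 - cf^(1/N).
pessimistic_error <- function(E, N, cf) {
  if (N == 0) return(0)
  if (E >= N) return(1)
  1 - stats::qbeta(cf, N - E, E + 1)
}

node_leaf_error <- function(node, cf) {
  n <- sum(node$counts)
  n * pessimistic_error(n - max(node$counts), n, cf)
}

prune_node <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  subtree_err <- sum_leaf_errors(node, cf)
  collapsed_err <- node_leaf_error(node, cf)
  if (collapsed_err <= subtree_err + 1e-9) {
    return(list(type = "leaf",
                class = names(node$counts)[which.max(node$counts)],
                counts = node$counts))
  }
  node
}

sum_leaf_errors <- function(node, cf) {
  if (node$type == "leaf") return(node_leaf_error(node, cf))
  sum_leaf_errors(node$left, cf) + sum_leaf_errors(node$right, cf)
}

tree_features <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

count_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

#' Predict class labels with a decision tree
#'
#' Rows are routed deterministically: values `<=` a node's threshold go
#' left, values `>` go right.
#'
#' @param object A `cspr_tree`.
#' @param newdata Numeric matrix or data.frame providing every feature the
#'   tree uses (missing ones are an error naming the feature).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.cspr_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  need <- setdiff(object$meta$features_used, colnames(newdata))
  if (length(need)) {
    stop("predict: missing feature(s): ", paste(need, collapse = ", "))
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (node$type == "split") {
      node <- if (newdata[i, node$feature] <= node$threshold) node$left
      else node$right
    }
    node$class
  }, character(1))
}

#' @export
print.cspr_tree <- function(x, ...) {
  cat("cspr_tree:", count_leaves(x$root), "leaves, trained on",
      x$meta$n_rows, "rows\n")
  cat(render_rules(x))
  invisible(x)
}

#' Extract if-then rules from a decision tree
#'
#' One rule per leaf, in left-to-right leaf order. The rules are mutually
#' exclusive and jointly exhaustive over the feature space.
#'
#' @param model A `cspr_tree`.
#' @return Object of class `cspr_rules`: list of rules, each with
#'   `conditions` (data.frame `feature`, `op` (`<=` or `>`), `threshold`),
#'   `class` and `support` (training rows at the leaf).
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "cspr_tree"))
  rules <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      rules[[length(rules) + 1]] <<- list(conditions = conds,
                                          class = node$class,
                                          support = sum(node$counts))
      return(invisible())
    }
    walk(node$left, rbind(conds, data.frame(
      feature = node$feature, op = "<=", threshold = node$threshold,
      stringsAsFactors = FALSE)))
    walk(node$right, rbind(conds, data.frame(
      feature = node$feature, op = ">", threshold = node$threshold,
      stringsAsFactors = FALSE)))
  }
  walk(model$root, data.frame(feature = character(0), op = character(0),
                              threshold = numeric(0),
                              stringsAsFactors = FALSE))
  structure(rules, class = "cspr_rules")
}

#' Predict with an extracted rule list
#'
#' @param object A `cspr_rules` object.
#' @param newdata Matrix or data.frame of features.
#' @param ... Unused.
#' @return Character vector of labels (the class of the first — and, by
#'   construction, only — matching rule per row).
#' @export
predict.cspr_rules <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    for (rule in object) {
      cond <- rule$conditions
      hit <- TRUE
      for (c_i in seq_len(nrow(cond))) {
        v <- newdata[i, cond$feature[c_i]]
        ok <- if (cond$op[c_i] == "<=") v <= cond$threshold[c_i]
        else v > cond$threshold[c_i]
        if (!ok) { hit <- FALSE; break }
      }
      if (hit) return(rule$class)
    }
    NA_character_
  }, character(1))
}

#' Render rules as indented if-then text
#'
#' One line per rule; the indentation mirrors the depth of the leaf in the
#' tree, in the style of published rule trees.
#'
#' @param model A `cspr_tree` or `cspr_rules` object.
#' @return A single character string (lines separated by newlines).
#' @export
render_rules <- function(model) {
  rules <- if (inherits(model, "cspr_tree")) extract_rules(model) else model
  stopifnot(inherits(rules, "cspr_rules"))
  lines <- vapply(rules, function(rule) {
    cond <- rule$conditions
    lhs <- if (nrow(cond) == 0) "TRUE" else
      paste(cond$feature, cond$op,
            vapply(cond$threshold, format_num, character(1)),
            collapse = " & ")
    indent <- strrep("  ", max(0, nrow(cond) - 1))
    sprintf("%s%s -> %s [n=%d]", indent, lhs, rule$class, rule$support)
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

format_num <- function(v) {
  s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
  s
}

#' Parse rendered rule text back into a rule list
#'
#' Inverse of [render_rules()]: `parse_rules(render_rules(r))` reproduces
#' `r`.
#'
#' @param text Character string or vector of lines.
#' @return A `cspr_rules` object.
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines[nzchar(trimws(lines))])
  rules <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^(.*) -> (\\S+) \\[n=(\\d+)\\]$", ln))[[1]]
    if (length(m) != 4) stop("parse_rules: malformed line: ", ln)
    lhs <- trimws(m[2])
    if (lhs == "TRUE") {
      conds <- data.frame(feature = character(0), op = character(0),
                          threshold = numeric(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(lhs, " & ", fixed = TRUE)[[1]]
      toks <- strsplit(parts, " +")
      conds <- data.frame(
        feature = vapply(toks, `[`, character(1), 1),
        op = vapply(toks, `[`, character(1), 2),
        threshold = as.numeric(vapply(toks, `[`, character(1), 3)),
        stringsAsFactors = FALSE)
    }
    list(conditions = conds, class = m[3], support = as.integer(m[4]))
  })
  structure(rules, class = "cspr_rules")
}
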