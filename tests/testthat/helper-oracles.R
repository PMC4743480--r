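# Independent oracles and small fixtures shared across tests.

# quick feature_table from vectors/matrices
make_ft <- function(x, labels, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  feature_table(x, labels, positive = positive)
}

# Naive entropy in bits
oracle_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  h <- 0
  for (c_ in counts) {
    if (c_ > 0) h <- h - (c_ / n) * log2(c_ / n)
  }
  h
}

# Exhaustive gain-ratio search over every feature and every candidate
# threshold (midpoints of adjacent distinct values whose value groups are
# not both pure with the same class). Written with plain loops,
# independent of the inducer's vectorized path. Returns NULL or
# list(feature, threshold, gain_ratio).
oracle_best_split <- function(x, y, min_leaf = 1) {
  y <- factor(y)
  n <- nrow(x)
  classes <- levels(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    for (vi in seq_len(length(vals) - 1)) {
      g1 <- y[x[, j] == vals[vi]]
      g2 <- y[x[, j] == vals[vi + 1]]
      pure_same <- length(unique(g1)) == 1 && length(unique(g2)) == 1 &&
        unique(as.character(g1)) == unique(as.character(g2))
      if (pure_same) next
      thr <- (vals[vi] + vals[vi + 1]) / 2
      left <- x[, j] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      cl <- sapply(classes, function(cc) sum(y[left] == cc))
      cr <- sapply(classes, function(cc) sum(y[!left] == cc))
      gain <- oracle_entropy(cl + cr) -
        (nl * oracle_entropy(cl) + nr * oracle_entropy(cr)) / n
      si <- oracle_entropy(c(nl, nr))
      if (si <= 0) next
      gr <- max(gain, 0) / si
      if (is.null(best) || gr > best$gain_ratio + 1e-10) {
        best <- list(feature = j, threshold = thr, gain_ratio = gr)
      }
    }
  }
  best
}

# Direct evaluation of the four statistics from first principles
oracle_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(accuracy = 100 * (tp + tn) / n,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Partition agreement up to cluster relabeling (2 clusters)
same_partition <- function(a, b) {
  identical(a == a[1], b == b[1])
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
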