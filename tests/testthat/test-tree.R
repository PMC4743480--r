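test_that("1-D toy set yields the single midpoint split", {
  ft <- make_ft(matrix(c(1, 2, 10, 11), ncol = 1,
                       dimnames = list(NULL, "x")),
                c("A", "A", "B", "B"))
  tr <- train_decision_tree(ft)
  expect_equal(tr$root$type, "split")
  expect_equal(tr$root$threshold, 6)
  expect_equal(predict(tr, ft$x), c("A", "A", "B", "B"))
  expect_length(extract_rules(tr), 2)
})

test_that("single-class input gives a single leaf", {
  ft <- make_ft(matrix(1:4, ncol = 1), rep("A", 4))
  tr <- train_decision_tree(ft)
  expect_equal(tr$root$type, "leaf")
  expect_equal(predict(tr, matrix(99, 1, 1,
                                  dimnames = list(NULL, "v1"))), "A")
})

test_that("XOR-like four points are solved at depth two", {
  ft <- make_ft(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2,
                       dimnames = list(NULL, c("a", "b"))),
                c("A", "B", "B", "A"))
  tr <- train_decision_tree(ft, min_leaf = 1, prune = FALSE)
  expect_equal(predict(tr, ft$x), c("A", "B", "B", "A"))
  expect_equal(length(extract_rules(tr)), 4)
})

test_that("inducer root split matches the exhaustive gain-ratio oracle", {
  set.seed(17)
  n_cases <- 250
  for (i in seq_len(n_cases)) {
    n <- sample(4:12, 1)
    p <- sample(1:2, 1)
    x <- matrix(sample(1:5, n * p, replace = TRUE) +
                  round(runif(n * p), 2), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    y <- factor(sample(c("A", "B"), n, replace = TRUE))
    if (length(unique(y)) < 2) next
    want <- oracle_best_split(x, y, min_leaf = 1)
    got <- pgpcspr:::best_split(x, y, min_leaf = 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature,
                   label = paste("case", i, "feature"))
      expect_equal(got$threshold, want$threshold, tolerance = 1e-12,
                   label = paste("case", i, "threshold"))
      expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-9)
    }
  }
})

test_that("boundary rows route left and missing features error", {
  # single-node rule mirroring a published molecular-weight cutoff
  tree <- structure(list(
    root = list(type = "split", feature = "MW", threshold = 668.78,
                counts = c(substrate = 3, non_substrate = 21),
                left = list(type = "leaf", class = "non_substrate",
                            counts = c(substrate = 0, non_substrate = 21)),
                right = list(type = "leaf", class = "substrate",
                             counts = c(substrate = 3, non_substrate = 0))),
    classes = c("substrate", "non_substrate"), positive = "substrate",
    meta = list(n_rows = 24, features_used = "MW",
                pruning_confidence = 0.25, min_leaf = 2)),
    class = "cspr_tree")
  newx <- matrix(c(692.80, 668.78, 100), ncol = 1,
                 dimnames = list(NULL, "MW"))
  expect_equal(predict(tree, newx),
               c("substrate", "non_substrate", "non_substrate"))
  expect_error(predict(tree, matrix(1, 1, 1, dimnames = list(NULL, "x"))),
               "MW")
})

test_that("pruning only simplifies and preserves pure-set predictions", {
  set.seed(23)
  for (i in 1:10) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    colnames(x) <- c("a", "b", "c")
    y <- ifelse(x[, 1] + 0.3 * rnorm(60) > 0, "pos", "neg")
    ft <- feature_table(x, y, positive = "pos")
    full <- train_decision_tree(ft, prune = FALSE)
    pruned <- train_decision_tree(ft, prune = TRUE)
    expect_lte(pgpcspr:::count_leaves(pruned$root),
               pgpcspr:::count_leaves(full$root))
  }
  # consistent (pure) training set: pruning must not change predictions
  xs <- matrix(c(1:6, 9:14), ncol = 1, dimnames = list(NULL, "x"))
  fts <- feature_table(xs, rep(c("A", "B"), each = 6))
  t_full <- train_decision_tree(fts, prune = FALSE)
  t_pr <- train_decision_tree(fts, prune = TRUE)
  expect_equal(predict(t_pr, xs), predict(t_full, xs))
  expect_equal(predict(t_pr, xs), rep(c("A", "B"), each = 6))
})

test_that("rules are equivalent to the tree and exhaustive on probes", {
  set.seed(31)
  x <- matrix(rnorm(200 * 3), 200, 3)
  colnames(x) <- c("a", "b", "c")
  y <- ifelse(x[, 1] > 0.2, ifelse(x[, 2] > 0, "pos", "neg"),
              ifelse(x[, 3] > 0.5, "pos", "neg"))
  ft <- feature_table(x, y, positive = "pos")
  tr <- train_decision_tree(ft)
  rules <- extract_rules(tr)
  probes <- matrix(rnorm(500 * 3, sd = 2), 500, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  via_rules <- predict(rules, probes)
  expect_false(anyNA(via_rules))            # exhaustive coverage
  expect_equal(via_rules, predict(tr, probes))
  # rule supports sum to the training size
  expect_equal(sum(vapply(rules, `[[`, numeric(1), "support")), 200)
})

test_that("rendered rule text round-trips through the parser", {
  set.seed(37)
  x <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("MW", "ALogP")))
  y <- ifelse(x[, 1] + x[, 2] > 0, "pos", "neg")
  tr <- train_decision_tree(feature_table(x, y, positive = "pos"))
  rules <- extract_rules(tr)
  back <- parse_rules(render_rules(tr))
  expect_equal(length(back), length(rules))
  for (i in seq_along(rules)) {
    expect_equal(back[[i]]$class, rules[[i]]$class)
    expect_equal(back[[i]]$support, rules[[i]]$support)
    expect_equal(back[[i]]$conditions$threshold,
                 rules[[i]]$conditions$threshold, tolerance = 1e-12)
    expect_equal(back[[i]]$conditions$op, rules[[i]]$conditions$op)
  }
  # single-leaf tree renders one unconditional line
  leaf_tree <- train_decision_tree(make_ft(matrix(1:3, ncol = 1),
                                           rep("A", 3)))
  expect_match(render_rules(leaf_tree), "^TRUE -> A \\[n=3\\]\\n$")
})
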