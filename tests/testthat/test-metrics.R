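test_that("confusion matrix tallies predictions against truths", {
  cm <- confusion(rep(c("pos", "neg"), c(3, 2)),
                  rep(c("pos", "neg"), c(3, 2)), positive = "pos")
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               c(TP = 3L, FP = 0L, FN = 0L, TN = 2L))

  inv <- confusion(c("neg", "neg", "neg", "pos", "pos"),
                   c("pos", "pos", "pos", "neg", "neg"), positive = "pos")
  expect_equal(unclass(inv)[c("TP", "FP", "FN", "TN")],
               c(TP = 0L, FP = 2L, FN = 3L, TN = 0L))

  # hand-built mixed 6-row case: tallied by hand
  pred <- c("pos", "pos", "neg", "neg", "pos", "neg")
  true <- c("pos", "neg", "pos", "neg", "pos", "neg")
  cm6 <- confusion(pred, true, positive = "pos")
  expect_equal(unclass(cm6)[c("TP", "FP", "FN", "TN")],
               c(TP = 2L, FP = 1L, FN = 1L, TN = 2L))

  expect_error(confusion(c("pos", "odd"), c("pos", "neg"), "pos"),
               "unknown")
  expect_error(confusion("pos", c("pos", "neg"), "pos"), "length")
})

test_that("the four statistics match their formulas", {
  perfect <- metrics(c(TP = 3, FP = 0, FN = 0, TN = 4))
  expect_equal(unname(perfect[["accuracy"]]), 100)
  expect_equal(unname(perfect[["sensitivity"]]), 100)
  expect_equal(unname(perfect[["specificity"]]), 100)
  expect_equal(unname(perfect[["mcc"]]), 1)

  inverted <- metrics(c(TP = 0, FP = 2, FN = 2, TN = 0))
  expect_equal(unname(inverted[["mcc"]]), -1)

  m <- metrics(c(TP = 90, FP = 10, FN = 20, TN = 80))
  expect_equal(unname(m[["accuracy"]]), 85)
  expect_equal(unname(m[["sensitivity"]]), 81.818, tolerance = 1e-4)
  expect_equal(unname(m[["specificity"]]), 88.889, tolerance = 1e-4)
  expect_equal(unname(m[["mcc"]]), 0.7035, tolerance = 1e-4)

  # random matrices against the first-principles oracle
  set.seed(41)
  for (i in 1:25) {
    cm <- c(TP = rpois(1, 20), FP = rpois(1, 8), FN = rpois(1, 8),
            TN = rpois(1, 20))
    if (sum(cm) == 0) next
    got <- suppressWarnings(metrics(cm))
    want <- oracle_metrics(cm["TP"], cm["FP"], cm["FN"], cm["TN"])
    expect_equal(unname(unclass(got)), unname(want), tolerance = 1e-12)
  }
})

test_that("MCC degenerate and symmetry properties hold", {
  # zero denominator factor -> 0 (specificity also degenerates here)
  expect_equal(unname(suppressWarnings(
    metrics(c(TP = 5, FP = 0, FN = 0, TN = 0)))[["mcc"]]), 0)
  # FP = FN = 0 -> 1
  expect_equal(unname(metrics(c(TP = 7, FP = 0, FN = 0, TN = 2))[["mcc"]]), 1)
  set.seed(5)
  for (i in 1:20) {
    v <- rpois(4, 10) + 1
    m1 <- metrics(c(TP = v[1], FP = v[2], FN = v[3], TN = v[4]))
    # swapping (TP<->FN, TN<->FP) negates MCC
    m2 <- metrics(c(TP = v[3], FP = v[4], FN = v[1], TN = v[2]))
    expect_equal(unname(m1[["mcc"]]), -unname(m2[["mcc"]]), tolerance = 1e-12)
    # class-label exchange (TP<->TN, FP<->FN) preserves MCC
    m3 <- metrics(c(TP = v[4], FP = v[3], FN = v[2], TN = v[1]))
    expect_equal(unname(m1[["mcc"]]), unname(m3[["mcc"]]), tolerance = 1e-12)
  }
  # undefined sensitivity reported as missing with a warning
  expect_warning(m <- metrics(c(TP = 0, FP = 2, FN = 0, TN = 3)),
                 "sensitivity")
  expect_true(is.na(m[["sensitivity"]]))
})

test_that("PCA-stratified split has exact sizes and seed determinism", {
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2)
  ft <- make_ft(x, rep(c("pos", "neg"), c(60, 40)), positive = "pos")
  plan <- pca_random_split(ft, 0.85, seed = 9)
  expect_length(plan$train_ids, 85)   # floor(.85*60+.5) + floor(.85*40+.5)
  expect_length(plan$test_ids, 15)
  expect_setequal(c(plan$train_ids, plan$test_ids), ft$ids)
  plan2 <- pca_random_split(ft, 0.85, seed = 9)
  expect_identical(plan$test_ids, plan2$test_ids)
  plan3 <- pca_random_split(ft, 0.85, seed = 10)
  expect_false(identical(sort(plan$test_ids), sort(plan3$test_ids)))
  expect_length(plan3$test_ids, 15)
})

test_that("bimodal PC1 contributes test rows from both modes", {
  set.seed(3)
  x <- rbind(matrix(rnorm(120, -8), 60, 2), matrix(rnorm(120, 8), 60, 2))
  colnames(x) <- c("a", "b")
  ft <- feature_table(x, rep("pos", 120), ids = paste0("r", 1:120))
  plan <- pca_random_split(ft, 0.85, seed = 4)
  test_idx <- match(plan$test_ids, ft$ids)
  expect_gt(sum(test_idx <= 60), 0)
  expect_gt(sum(test_idx > 60), 0)
})

test_that("k-fold CV partitions rows and pools predictions", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, -4), 20, 2), matrix(rnorm(40, 4), 20, 2))
  colnames(x) <- c("a", "b")
  ft <- feature_table(x, rep(c("pos", "neg"), each = 20), positive = "pos")
  rep10 <- kfold_cv(ft, learner_config("tree"), k = 10, seed = 2)
  folds <- attr(rep10, "folds")
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 40)
  # perfectly separable -> pooled MCC 1
  expect_equal(unname(rep10[["mcc"]]), 1)
  # leave-one-out: every row predicted exactly once
  loo <- kfold_cv(ft_rows(ft, c(1:5, 21:25)), learner_config("tree"),
                  k = 10, seed = 2)
  cm <- attr(loo, "confusion")
  expect_equal(sum(cm), 10)
})
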