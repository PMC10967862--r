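test_that("compute_metrics matches hand-checked confusion arithmetic", {
  # perfect and inverted predictors
  y <- c(1, 1, 1, 0, 0)
  m <- compute_metrics(y, c(0.9, 0.8, 0.7, 0.2, 0.1))
  expect_equal(m$auc, 1); expect_equal(m$bac, 1)
  expect_equal(m$fpr, 0); expect_equal(m$mcc, 1)
  m2 <- compute_metrics(y, c(0.1, 0.2, 0.3, 0.8, 0.9))
  expect_equal(m2$auc, 0); expect_equal(m2$mcc, -1)
  # confusion (TP=40, FN=10, FP=20, TN=30)
  y3 <- c(rep(1, 50), rep(0, 50))
  s3 <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 20), rep(0.1, 30))
  m3 <- compute_metrics(y3, s3)
  expect_equal(m3$bac, (0.8 + 0.6) / 2)
  expect_equal(m3$fpr, 0.4)
  expect_equal(m3$ppv, 2 / 3)
  expect_equal(m3$mcc, (40 * 30 - 20 * 10) /
                 sqrt(60) / sqrt(50) / sqrt(50) / sqrt(40))
  # labels accepted as strings
  expect_equal(compute_metrics(c("synergy", "antagonism"), c(0.9, 0.1))$bac, 1)
  expect_warning(compute_metrics(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("compute_metrics agrees with the brute-force oracle on random draws", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    m <- compute_metrics(y, s)
    o <- oracle_metrics(y, s)
    expect_equal(m$auc, o$auc, tolerance = 1e-12)
    expect_identical(m$bac, o$bac)
    expect_identical(m$ppv, o$ppv)
    expect_identical(m$fpr, o$fpr)
    expect_identical(m$mcc, o$mcc)
  }
})

test_that("fold plans are stratified, balanced and deterministic", {
  tab <- synergy_table(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10), "CL",
                       c(rep("synergy", 8), rep("antagonism", 2)))
  plan <- make_folds(tab, seed = 3)
  expect_equal(as.integer(table(plan$assignment)), rep(2L, 5))
  plan2 <- make_folds(tab, seed = 3)
  expect_identical(plan$assignment, plan2$assignment)
  expect_error(make_folds(tab[1:3], seed = 1), "at least 5")
  # class balance across folds on a larger set
  set.seed(7)
  big <- synergy_table(sprintf("A%03d", 1:500), sprintf("B%03d", 1:500),
                       "CL", sample(c("synergy", "antagonism"), 500, TRUE,
                                    prob = c(0.77, 0.23)))
  frac <- mean(big$label == "synergy")
  for (seed in 1:20) {
    p <- make_folds(big, seed = seed)
    fold_frac <- tapply(big$label == "synergy", p$assignment, mean)
    expect_true(all(abs(fold_frac - frac) <= 0.05))
  }
  # augmented rows are rejected
  big$provenance[1] <- "augmented"
  expect_error(make_folds(big, seed = 1), "original")
})

test_that("leakage-safe training sets exclude test-fold descendants", {
  b <- small_bundle()
  orig <- b$synergy
  aug <- augment_dataset(orig, b$library)
  for (seed in 1:20) {
    plan <- make_folds(orig, seed = seed)
    for (f in 1:5) {
      sets <- leakage_safe_train_set(f, plan, orig, aug)
      test_ids <- sets$test$id
      # test folds contain only originals
      expect_true(all(sets$test$provenance == "original"))
      # no augmented child of a test parent in training
      aug_rows <- sets$train[sets$train$provenance == "augmented"]
      expect_length(intersect(aug_rows$parent, test_ids), 0L)
      # every train-fold original's children are included
      train_orig <- sets$train[sets$train$provenance == "original"]
      expected_children <- aug[aug$parent %in% train_orig$id]
      expect_equal(nrow(aug_rows), nrow(expected_children))
    }
  }
  # unresolvable parent errors
  bad <- data.table::copy(aug)
  bad$parent[1] <- "ghost|ghost|CL"
  plan <- make_folds(orig, seed = 1)
  expect_error(leakage_safe_train_set(1, plan, orig, bad), "unresolvable")
  # no augmentation: training set is the train-fold originals
  sets <- leakage_safe_train_set(1, plan, orig, NULL)
  expect_equal(nrow(sets$train) + nrow(sets$test), nrow(orig))
})

test_that("roc_points traces the empirical ROC", {
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.6, 0.7, 0.2)
  r <- roc_points(y, s)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # trapezoid area under the curve equals the rank-statistic AUC
  auc_trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(auc_trap, compute_metrics(y, s)$auc)
  expect_error(roc_points(c(1, 1), c(0.1, 0.9)), "single-class")
})

majority_spec <- list(
  fit = function(train) mean(train$label == "synergy") >= 0.5,
  predict = function(model, tab) rep(if (model) 0.75 else 0.25, nrow(tab))
)

test_that("cross_validate reports the full metric schema", {
  b <- small_bundle()
  cv <- suppressWarnings(
    cross_validate(majority_spec, b$synergy, seed = 2))
  expect_named(cv$mean, c("auc", "bac", "ppv", "fpr", "mcc", "delta_bac"))
  # degenerate always-majority classifier has BAC 0.5
  expect_equal(unname(cv$mean["bac"]), 0.5)
  expect_equal(nrow(cv$per_fold), 5L)
  # mean recomputable from per-fold values
  expect_equal(unname(cv$mean["bac"]), mean(cv$per_fold$bac))
  # report schema
  f <- tempfile(fileext = ".csv")
  rep <- write_cv_report(list("Majority/Original" = cv), f)
  expect_equal(names(rep), c("Classifier", "Dataset", "AUC", "BAC", "PPV",
                             "FPR", "MCC", "dBAC"))
  # per-group breakdown
  groups <- stats::setNames(rep(c("g1", "g2"), 2), names(b$profiles))
  cv2 <- suppressWarnings(
    cross_validate(majority_spec, b$synergy, seed = 2, groups = groups))
  expect_true(all(c("g1", "g2") %in% names(cv2$by_group)))
})

test_that("independent validation is a fixed single pass", {
  b <- small_bundle()
  model <- majority_spec$fit(b$synergy)
  # skewed external shape (6 positive / 49 negative) produces finite metrics
  ext <- synergy_table(sprintf("X%02d", 1:55), sprintf("Y%02d", 1:55), "CL",
                       c(rep("synergy", 6), rep("antagonism", 49)))
  m1 <- independent_validate(model, majority_spec, ext)
  m2 <- independent_validate(model, majority_spec, ext)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(all(is.finite(c(m1$bac, m1$ppv, m1$fpr, m1$mcc))))
})
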