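# Metrics and the leakage-safe stratified 5-fold cross-validation harness.
# Augmented instances only ever enter a fold's training set when their parent
# original lies in that training fold; test folds contain exclusively
# original instances.

label_to_binary <- function(label) {
  if (is.character(label) || is.factor(label)) {
    as.integer(as.character(label) == "synergy")
  } else {
    as.integer(label)
  }
}

#' Classification metrics for imbalanced binary problems
#'
#' Computes AUC (rank statistic with mid-rank tie handling, the
#' Mann-Whitney equivalence), and from the confusion matrix at `threshold`:
#' balanced accuracy BAC = (TPR + TNR)/2, precision PPV, false positive rate
#' FPR, and the Matthews correlation coefficient MCC. Ratios with a zero
#' denominator are reported as 0 and flagged. The synergy class is positive.
#'
#' @param labels binary 0/1 vector, or `"synergy"`/`"antagonism"` strings.
#' @param scores predicted probability of the positive class, in \[0, 1\].
#' @param threshold decision threshold on `scores` (default 0.5).
#' @return an object of class `synergy_metrics`: `auc`, `bac`, `ppv`, `fpr`,
#'   `mcc`, confusion counts `tp fp fn tn`, and `flags` (character vector of
#'   degenerate-denominator warnings).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- label_to_binary(labels)
  if (length(y) != length(scores)) stop("labels/scores length mismatch")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  flags <- character(0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class label vector: AUC undefined")
    auc <- NA_real_
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      0
    } else num / den
  }
  tpr <- safe_div(tp, tp + fn, "tpr")
  tnr <- safe_div(tn, tn + fp, "tnr")
  structure(list(
    auc = auc,
    bac = (tpr + tnr) / 2,
    ppv = safe_div(tp, tp + fp, "ppv"),
    fpr = safe_div(fp, fp + tn, "fpr"),
    mcc = mcc_from_counts(tp, fp, fn, tn),
    tp = tp, fp = fp, fn = fn, tn = tn,
    flags = flags
  ), class = "synergy_metrics")
}

#' @export
print.synergy_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f | BAC %.3f | PPV %.3f | FPR %.3f | MCC %.3f\n",
              x$auc, x$bac, x$ppv, x$fpr, x$mcc))
  invisible(x)
}

#' Stratified k-fold plan over original instances
#'
#' Assigns each original instance to one of `k` folds. With
#' `stratified = TRUE` (default) class proportions are balanced across
#' folds; fold sizes differ by at most one within each class. Deterministic
#' per seed.
#'
#' @param originals a synergy table containing only original instances.
#' @param seed integer RNG seed.
#' @param k number of folds (default 5).
#' @param stratified logical.
#' @return an object of class `fold_plan`: `assignment` (integer vector
#'   parallel to `originals`), `k`, `seed`, `stratified`.
#' @export
make_folds <- function(originals, seed, k = 5L, stratified = TRUE) {
  n <- nrow(originals)
  if (n < k) stop("need at least ", k, " instances for ", k, "-fold CV")
  if (any(originals$provenance != "original")) {
    stop("fold plans are built on original instances only")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignment <- integer(n)
  if (stratified) {
    y <- label_to_binary(originals$label)
    start <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      # continue the round-robin across classes so overall fold sizes
      # differ by at most one as well as within-class sizes
      assignment[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  } else {
    assignment[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_plan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Leakage-safe training and test sets for one fold
#'
#' The training set is the union of the training-fold originals and those
#' augmented instances whose parent id resolves to a training-fold original;
#' the test set comprises exclusively the held-out fold's originals, so no
#' augmented descendant of a test instance can leak into training.
#'
#' @param fold fold index in `1..k`.
#' @param plan a [make_folds()] plan.
#' @param originals the synergy table the plan was built on.
#' @param augmented optional synergy table of augmented instances (provenance
#'   `"augmented"`, resolvable `parent` ids).
#' @return list with synergy tables `train` and `test`.
#' @export
leakage_safe_train_set <- function(fold, plan, originals, augmented = NULL) {
  test <- originals[plan$assignment == fold]
  train <- originals[plan$assignment != fold]
  if (!is.null(augmented) && nrow(augmented) > 0) {
    unresolved <- setdiff(augmented$parent, originals$id)
    if (length(unresolved) > 0) {
      stop("augmented instance with unresolvable parent id: ", unresolved[1])
    }
    keep <- augmented[augmented$parent %in% train$id]
    train <- data.table::rbindlist(list(train, keep))
  }
  list(train = train, test = test)
}

#' Cross-validate a classifier with leakage-safe augmentation
#'
#' Runs stratified k-fold cross-validation. Per fold the classifier is
#' fitted on the (optionally augmented) training set and scored on the
#' held-out originals; per-fold AUC, BAC, PPV, FPR, MCC and
#' `delta_bac = train BAC - test BAC` (the overfitting gap) are reported
#' together with their mean and standard deviation. An optional
#' `groups` mapping (cell line -> group, e.g. tissue) adds pooled per-group
#' test metrics.
#'
#' @param spec a classifier spec: `list(fit = function(train_table) model,
#'   predict = function(model, table) scores)`, scores being positive-class
#'   probabilities.
#' @param originals synergy table of original instances.
#' @param augmented optional synergy table of augmented instances.
#' @param seed RNG seed (fold plan and any classifier randomness derived
#'   from it).
#' @param k number of folds.
#' @param stratified logical, see [make_folds()].
#' @param groups optional named character vector cell_line -> group.
#' @return an object of class `cv_result`: `per_fold` (data.frame), `mean`,
#'   `sd`, `plan`, optional `by_group`.
#' @export
cross_validate <- function(spec, originals, augmented = NULL, seed = 1L,
                           k = 5L, stratified = TRUE, groups = NULL) {
  plan <- make_folds(originals, seed = seed, k = k, stratified = stratified)
  cols <- c("auc", "bac", "ppv", "fpr", "mcc", "delta_bac")
  per_fold <- matrix(NA_real_, nrow = k, ncol = length(cols),
                     dimnames = list(NULL, cols))
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  pooled_cells <- character(0)
  for (f in seq_len(k)) {
    sets <- leakage_safe_train_set(f, plan, originals, augmented)
    model <- spec$fit(sets$train)
    test_scores <- spec$predict(model, sets$test)
    m_test <- compute_metrics(sets$test$label, test_scores)
    train_scores <- spec$predict(model, sets$train)
    m_train <- suppressWarnings(compute_metrics(sets$train$label, train_scores))
    per_fold[f, ] <- c(m_test$auc, m_test$bac, m_test$ppv, m_test$fpr,
                       m_test$mcc, m_train$bac - m_test$bac)
    pooled_scores <- c(pooled_scores, test_scores)
    pooled_labels <- c(pooled_labels, sets$test$label)
    pooled_cells <- c(pooled_cells, sets$test$cell_line)
  }
  per_fold <- as.data.frame(per_fold)
  per_fold$fold <- seq_len(k)
  by_group <- NULL
  if (!is.null(groups)) {
    grp <- unname(groups[pooled_cells])
    grp[is.na(grp)] <- "Other"
    by_group <- lapply(split(seq_along(grp), grp), function(i) {
      suppressWarnings(compute_metrics(pooled_labels[i], pooled_scores[i]))
    })
  }
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[cols]),
    sd = apply(per_fold[cols], 2, stats::sd),
    plan = plan,
    by_group = by_group
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("5-fold cross-validation (mean +/- sd over folds):\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Write a Table-2-style CV report
#'
#' CSV columns `Classifier, Dataset, AUC, BAC, PPV, FPR, MCC, dBAC`.
#'
#' @param results named list of `cv_result`s; names like
#'   `"RF/Original"` are split on `/` into Classifier and Dataset.
#' @param path output CSV path.
#' @return invisibly, the report data.frame.
#' @export
write_cv_report <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    m <- results[[nm]]$mean
    data.frame(Classifier = parts[1],
               Dataset = if (length(parts) > 1) parts[2] else "",
               AUC = m[["auc"]], BAC = m[["bac"]], PPV = m[["ppv"]],
               FPR = m[["fpr"]], MCC = m[["mcc"]], dBAC = m[["delta_bac"]])
  })
  report <- do.call(rbind, rows)
  data.table::fwrite(report, path)
  invisible(report)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct score threshold, for plotting
#' per-fold ROC curves.
#'
#' @inheritParams compute_metrics
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold (origin to top-right).
#' @export
roc_points <- function(labels, scores) {
  y <- label_to_binary(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("ROC undefined for single-class labels")
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0))
}

#' Published cross-validated reference performance
#'
#' The benchmark 5-fold CV metrics of the random-forest baseline and the
#' graph network on the AZ-DREAM synergy collection (original vs
#' original+augmented training), shipped as package data for comparison and
#' reporting.
#'
#' @return a data.frame with columns `classifier, dataset, auc, bac, ppv,
#'   fpr, mcc, delta_bac`.
#' @export
reference_performance <- function() {
  as.data.frame(data.table::fread(
    system.file("extdata", "reference_performance.tsv",
                package = "synergnet"),
    sep = "\t"))
}

#' Augmentation gains from a performance table
#'
#' Differences (combined-training minus original-training rows) per
#' classifier and metric, in absolute percentage points.
#'
#' @param tab a performance table shaped like [reference_performance()].
#' @param classifier which classifier's rows to difference.
#' @return named numeric vector of gains (percentage points) for `auc`,
#'   `bac`, `ppv`, `fpr`, `mcc`.
#' @export
augmentation_gains <- function(tab = reference_performance(),
                               classifier = "SynerGNet") {
  rows <- tab[tab$classifier == classifier, ]
  orig <- rows[rows$dataset == "original", ]
  comb <- rows[rows$dataset == "combined", ]
  if (nrow(orig) != 1 || nrow(comb) != 1) {
    stop("need exactly one original and one combined row for ", classifier)
  }
  metrics <- c("auc", "bac", "ppv", "fpr", "mcc")
  round(100 * (unlist(comb[metrics]) - unlist(orig[metrics])), 10)
}

#' Single-pass evaluation on an external validation set
#'
#' Applies a fitted model to instances outside the CV universe (no
#' refitting) and returns [compute_metrics()] output. Degenerate class
#' shapes (e.g. very few positives) are handled by the metric conventions:
#' zero-denominator ratios come back 0 with a flag rather than NaN.
#'
#' @param model a fitted model.
#' @param spec the classifier spec the model came from (its `predict` is
#'   used).
#' @param external a synergy table of external instances.
#' @return a `synergy_metrics` object.
#' @export
independent_validate <- function(model, spec, external) {
  scores <- spec$predict(model, external)
  compute_metrics(external$label, scores)
}
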