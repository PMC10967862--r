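# Traditional-ML baseline: each reduced graph is vectorized (degree-sorted
# nodes, per-feature standardization fitted on training data, projection to
# 32 principal components, row-major flattening to a fixed length) and fed
# to a random-forest classifier. No random-forest package exists in the
# target environment, so a compact bagged-CART forest (gini splits, mtry
# feature subsampling) is implemented here.

#' Degree-descending node order
#'
#' Nodes sorted by degree descending, ties broken by node id ascending, so
#' the sequence is deterministic across runs and platforms.
#'
#' @param g a graph with `nodes` and `edges` fields.
#' @return character vector of node ids.
#' @export
sort_nodes <- function(g) {
  deg <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    t1 <- table(g$edges[, 1]); t2 <- table(g$edges[, 2])
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  g$nodes[order(-deg, g$nodes)]
}

#' Fit / apply per-feature standardization
#'
#' `x_hat = (x - mu) / delta` per feature, with mean and standard deviation
#' fitted on training-set node features only. Zero-variance features get
#' `delta = 1` (they standardize to 0 rather than dividing by zero).
#'
#' @param X numeric matrix (rows = nodes pooled over training graphs).
#' @return a `standardizer` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  dv <- apply(X, 2, stats::sd)
  dv[!is.finite(dv) | dv == 0] <- 1
  structure(list(mean = mu, sd = dv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a fitted `standardizer`.
#' @export
standardize <- function(X, params) {
  if (!inherits(params, "standardizer")) stop("unfitted standardizer")
  sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
}

#' Fit a PCA projection
#'
#' Exact singular-value decomposition of the (already standardized)
#' training node-feature matrix, keeping the top `k` components by explained
#' variance. Errors when the matrix rank cannot support `k` components.
#'
#' @param X numeric matrix.
#' @param k number of components (default 32).
#' @return a `pca_model`: `center`, `rotation` (p x k, orthonormal columns),
#'   `explained` (variance fractions).
#' @export
fit_pca <- function(X, k = 32L) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < k) {
    stop("data rank ", rank, " < ", k,
         " components; use fewer components or more data")
  }
  tot <- sum(sv$d^2)
  structure(list(center = ctr,
                 rotation = sv$v[, seq_len(k), drop = FALSE],
                 explained = sv$d[seq_len(k)]^2 / tot),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param pca a fitted `pca_model`.
#' @export
pca_project <- function(X, pca) {
  sweep(X, 2, pca$center) %*% pca$rotation
}

#' Flattened fixed-length vector length
#' @param n_nodes node count; @param k components per node.
#' @return `k * n_nodes`.
#' @export
flat_vector_length <- function(n_nodes, k = 32L) as.numeric(k) * n_nodes

#' Vectorize one graph to a fixed-length flat vector
#'
#' Sort nodes by descending degree, standardize their features with the
#' training-fitted parameters, project to the PCA components, flatten
#' row-major in sorted node order, then zero-pad or truncate to `n_fix`
#' nodes, giving a constant `k * n_fix` length across a dataset.
#'
#' @param g a graph with `nodes`, `edges`, `features`.
#' @param params a fitted `standardizer`.
#' @param pca a fitted `pca_model`.
#' @param n_fix fixed node count after pad/truncate.
#' @return numeric vector of length `ncol(rotation) * n_fix`.
#' @export
vectorize_graph <- function(g, params, pca, n_fix) {
  ord <- sort_nodes(g)
  Z <- pca_project(standardize(g$features[ord, , drop = FALSE], params), pca)
  k <- ncol(Z)
  if (nrow(Z) >= n_fix) {
    Z <- Z[seq_len(n_fix), , drop = FALSE]
  } else {
    Z <- rbind(Z, matrix(0, n_fix - nrow(Z), k))
  }
  as.numeric(t(Z))
}

#' Fit the graph vectorizer on training graphs only
#'
#' Pools node features of the training graphs, fits the standardizer and
#' PCA, and records the fitted instance ids; `strict_exclude` enforces the
#' leakage rule by erroring if any supplied id belongs to the excluded
#' (test) set.
#'
#' @param graph_store named list id -> graph.
#' @param ids training instance ids.
#' @param k PCA components.
#' @param n_fix fixed node count; default the maximum node count over the
#'   whole store (keeps lengths consistent between folds).
#' @param strict_exclude ids that must not participate in fitting.
#' @return a `graph_vectorizer`: `standardizer`, `pca`, `n_fix`,
#'   `fitted_ids`.
#' @export
fit_vectorizer <- function(graph_store, ids, k = 32L, n_fix = NULL,
                           strict_exclude = NULL) {
  leak <- intersect(ids, strict_exclude)
  if (length(leak) > 0) {
    stop("leakage: vectorizer fitted on held-out instance ", leak[1])
  }
  feats <- do.call(rbind, lapply(graph_store[unique(ids)], `[[`, "features"))
  std <- fit_standardizer(feats)
  pca <- fit_pca(standardize(feats, std), k = k)
  if (is.null(n_fix)) {
    n_fix <- max(vapply(graph_store, function(g) length(g$nodes), 0L))
  }
  structure(list(standardizer = std, pca = pca, n_fix = n_fix,
                 fitted_ids = unique(ids)),
            class = "graph_vectorizer")
}

#' @rdname fit_vectorizer
#' @param vec a fitted `graph_vectorizer`; @param g a graph.
#' @export
apply_vectorizer <- function(vec, g) {
  vectorize_graph(g, vec$standardizer, vec$pca, vec$n_fix)
}

# ---- random forest -------------------------------------------------------

best_split <- function(X, y, feat_idx, min_leaf) {
  n <- length(y)
  n1 <- sum(y)
  best <- list(gain = -Inf)
  parent_gini <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
  for (j in feat_idx) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    cumn <- seq_len(n)
    valid <- which(xs[-n] < xs[-1])
    valid <- valid[cumn[valid] >= min_leaf & (n - cumn[valid]) >= min_leaf]
    if (length(valid) == 0) next
    nl <- cumn[valid]; l1 <- cum1[valid]
    nr <- n - nl; r1 <- n1 - l1
    gl <- 1 - (l1 / nl)^2 - ((nl - l1) / nl)^2
    gr <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
    gain <- parent_gini - (nl * gl + nr * gr) / n
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
    }
  }
  best
}

grow_tree <- function(X, y, mtry, max_depth, min_split, min_leaf) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- numeric(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- -1L
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- NA_real_
    length(feature)
  }
  build <- function(idx, depth) {
    node <- new_node()
    yy <- y[idx]
    p1 <- mean(yy)
    pred[node] <<- p1
    if (depth >= max_depth || length(idx) < min_split ||
        p1 == 0 || p1 == 1) {
      return(node)
    }
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    sp2 <- best_split(X[idx, feats, drop = FALSE], yy, seq_along(feats),
                      min_leaf)
    if (!is.finite(sp2$gain) || sp2$gain <= 1e-12) return(node)
    j <- feats[sp2$feature]
    go_left <- X[idx, j] <= sp2$threshold
    feature[node] <<- j
    threshold[node] <<- sp2$threshold
    left[node] <<- build(idx[go_left], depth + 1L)
    right[node] <<- build(idx[!go_left], depth + 1L)
    node
  }
  build(seq_along(y), 0L)
  list(feature = feature, threshold = threshold, left = left,
       right = right, pred = pred)
}

predict_tree <- function(tree, newdata) {
  X <- newdata
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree$feature[node] != -1L) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node]) {
        tree$left[node]
      } else tree$right[node]
    }
    out[i] <- tree$pred[node]
  }
  out
}

#' Train a random-forest classifier
#'
#' Bagged CART trees with gini impurity splits and per-node random feature
#' subsampling (`mtry`, default `sqrt(p)`); scores are the mean of the
#' trees' leaf class-1 proportions. Deterministic given the seed.
#'
#' @param X numeric feature matrix (rows = instances).
#' @param y 0/1 labels (or synergy/antagonism strings).
#' @param n_trees number of trees.
#' @param mtry features tried per split.
#' @param max_depth,min_split,min_leaf tree-growth controls.
#' @param seed RNG seed.
#' @return a `synergy_rf` model.
#' @export
train_rf <- function(X, y, n_trees = 100L, mtry = NULL, max_depth = 12L,
                     min_split = 4L, min_leaf = 1L, seed = 1L) {
  y <- label_to_binary(y)
  if (nrow(X) != length(y)) stop("inconsistent vector lengths")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (b in seq_len(n_trees)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y[idx], mtry,
                              max_depth, min_split, min_leaf)
    }
  })
  structure(list(trees = trees, p = ncol(X), seed = seed),
            class = "synergy_rf")
}

#' @rdname train_rf
#' @param model a `synergy_rf`.
#' @return `predict_rf`: numeric scores in \[0, 1\].
#' @export
predict_rf <- function(model, X) {
  if (ncol(X) != model$p) stop("inconsistent vector lengths")
  preds <- vapply(model$trees, predict_tree, numeric(nrow(X)), newdata = X)
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Classifier spec wrapping vectorization + random forest
#'
#' The vectorizer (standardizer + PCA) is fitted inside `fit()` on the
#' training fold only, satisfying the leakage rule.
#'
#' @param graph_store named list instance id -> reduced graph.
#' @param k PCA components (default 32).
#' @param n_fix fixed node count (default max over store).
#' @param n_trees,max_depth forest controls.
#' @param seed RNG seed.
#' @return a spec `list(fit, predict)` for [cross_validate()].
#' @export
rf_classifier <- function(graph_store, k = 32L, n_fix = NULL, n_trees = 60L,
                          max_depth = 10L, seed = 1L) {
  if (is.null(n_fix)) {
    n_fix <- max(vapply(graph_store, function(g) length(g$nodes), 0L))
  }
  vec_mat <- function(vec, tab) {
    t(vapply(tab$id, function(id) apply_vectorizer(vec, graph_store[[id]]),
             numeric(ncol(vec$pca$rotation) * vec$n_fix)))
  }
  list(
    fit = function(train_tab) {
      vec <- fit_vectorizer(graph_store, train_tab$id, k = k, n_fix = n_fix)
      X <- vec_mat(vec, train_tab)
      rf <- train_rf(X, train_tab$label, n_trees = n_trees,
                     max_depth = max_depth, seed = seed)
      list(vec = vec, rf = rf)
    },
    predict = function(model, tab) {
      predict_rf(model$rf, vec_mat(model$vec, tab))
    }
  )
}
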