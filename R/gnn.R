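# The graph classifier: a cascade of two graph convolutional modules
# (generalized-aggregation convolution -> batch normalization -> ReLU),
# jumping-knowledge concatenation of both modules' node embeddings, a
# graph-level readout concatenating node-wise maximum and mean, and a
# two-layer MLP head with batch norm, ReLU and dropout, ending in two
# logits (synergy vs antagonism).
#
# No deep-learning backend is available in the target environment, so the
# forward pass, backpropagation, and the Adam optimizer are implemented
# directly with dense matrix algebra. Each convolution projects node
# features, aggregates ReLU-positive neighbor messages with a channel-wise
# softmax weighting (learnable inverse temperature; "mean" available as a
# simpler aggregator), and mixes self and aggregate through a linear layer.

#' GNN model configuration
#'
#' @param in_dim input node-feature dimensionality (218).
#' @param hidden_dim conv-module width (default 64).
#' @param head_hidden prediction-head hidden width (default 64).
#' @param dropout_rate dropout probability in the head, in \[0, 1).
#' @param aggregator `"softmax"` (learnable-temperature softmax weighting,
#'   default) or `"mean"`.
#' @param jk_mode jumping-knowledge mode; only `"concat"` (lossless) is
#'   implemented.
#' @param n_classes fixed 2.
#' @return a list of class `model_config`.
#' @export
model_config <- function(in_dim = 218L, hidden_dim = 64L, head_hidden = 64L,
                         dropout_rate = 0.5, aggregator = c("softmax", "mean"),
                         jk_mode = "concat", n_classes = 2L) {
  aggregator <- match.arg(aggregator)
  stopifnot(in_dim > 0, hidden_dim > 0, head_hidden > 0,
            dropout_rate >= 0, dropout_rate < 1,
            jk_mode == "concat", n_classes == 2L)
  structure(as.list(environment()), class = "model_config")
}

#' Training configuration
#'
#' @param epochs fixed-length training run (default 200; no early stopping).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param seed RNG seed; recorded in the trained model.
#' @param class_weighting weight the cross-entropy inversely to class
#'   frequency (default TRUE; synergy data run ~77/23).
#' @param weight_decay decoupled L2 penalty on the weight matrices (not on
#'   biases or batch-norm parameters); part of the model's regularization
#'   alongside dropout and batch norm.
#' @param verbose print loss every `verbose` epochs (0 = silent).
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-3,
                         batch_size = 32L, seed = 1L, class_weighting = TRUE,
                         weight_decay = 5e-4, verbose = 0L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            weight_decay >= 0)
  structure(as.list(environment()), class = "train_config")
}

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

#' Build an untrained GNN model
#'
#' Initializes all parameters (Glorot-uniform weights, unit batch-norm
#' gains) under the given seed.
#'
#' @param cfg a [model_config()].
#' @param seed initialization seed.
#' @return an object of class `synergnet_model` holding `params` (named
#'   list), batch-norm running statistics, and the config.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  h <- cfg$hidden_dim; p <- cfg$head_hidden
  with_seed(seed, {
    params <- list(
      W1 = glorot(cfg$in_dim, h), b1 = numeric(h),
      U1 = glorot(h, h), c1 = numeric(h),
      beta1 = 1,
      g1 = rep(1, h), d1 = numeric(h),
      W2 = glorot(h, h), b2 = numeric(h),
      U2 = glorot(h, h), c2 = numeric(h),
      beta2 = 1,
      g2 = rep(1, h), d2 = numeric(h),
      W3 = glorot(4 * h, p), b3 = numeric(p),
      g3 = rep(1, p), d3 = numeric(p),
      W4 = glorot(p, cfg$n_classes), b4 = numeric(cfg$n_classes)
    )
    running <- list(
      bn1 = list(mean = numeric(h), var = rep(1, h)),
      bn2 = list(mean = numeric(h), var = rep(1, h)),
      bn3 = list(mean = numeric(p), var = rep(1, p))
    )
    structure(list(params = params, running = running, cfg = cfg,
                   seed = seed, trained = FALSE, history = NULL),
              class = "synergnet_model")
  })
}

#' Total trainable parameter count
#' @param model a `synergnet_model`.
#' @return integer.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Convert a reduced graph to the GNN input form
#'
#' @param rg a `reduced_graph` (or any graph with `nodes`, `edges`,
#'   `features`).
#' @param label optional `"synergy"`/`"antagonism"` or 0/1 override; default
#'   taken from the graph's instance.
#' @return a `gnn_graph`: `x` (n x in_dim matrix), `edge_index` (2-row
#'   integer matrix, both directions), `n`, `y` (0/1 or NA).
#' @export
as_gnn_graph <- function(rg, label = NULL) {
  idx <- stats::setNames(seq_along(rg$nodes), rg$nodes)
  ed <- rg$edges
  ei <- if (nrow(ed) > 0) {
    u <- idx[ed[, 1]]; v <- idx[ed[, 2]]
    rbind(c(u, v), c(v, u))
  } else matrix(integer(0), nrow = 2)
  if (is.null(label)) label <- rg$instance$label
  y <- if (is.null(label) || is.na(label)) NA_integer_ else label_to_binary(label)
  structure(list(x = unname(rg$features), edge_index = ei,
                 n = length(rg$nodes), y = y), class = "gnn_graph")
}

collate_batch <- function(graphs) {
  ns <- vapply(graphs, `[[`, 0L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "x"))
  src <- unlist(lapply(seq_along(graphs),
                       function(i) graphs[[i]]$edge_index[1, ] + offs[i]))
  dst <- unlist(lapply(seq_along(graphs),
                       function(i) graphs[[i]]$edge_index[2, ] + offs[i]))
  gid <- rep(seq_along(graphs), ns)
  list(X = X, src = as.integer(src), dst = as.integer(dst), gid = gid,
       n = nrow(X), g = length(graphs),
       node_split = split(seq_len(nrow(X)), gid))
}

scatter_rowsum <- function(values, group, n) {
  out <- matrix(0, n, ncol(values))
  if (nrow(values) > 0) {
    r <- rowsum(values, group)
    out[as.integer(rownames(r)), ] <- r
  }
  out
}

agg_forward <- function(Z, src, dst, n, beta, aggregator) {
  if (length(src) == 0) {
    return(list(A = matrix(0, n, ncol(Z)), cache = NULL))
  }
  msg <- pmax(Z[src, , drop = FALSE], 0) + 1e-7
  if (aggregator == "softmax") {
    expo <- exp(pmin(pmax(beta * msg, -30), 30))
    denom <- scatter_rowsum(expo, dst, n)
    s <- expo / denom[dst, , drop = FALSE]
    A <- scatter_rowsum(s * msg, dst, n)
    list(A = A, cache = list(msg = msg, s = s))
  } else {
    cnt <- tabulate(dst, n)
    cnt[cnt == 0] <- 1
    A <- scatter_rowsum(msg, dst, n) / cnt
    list(A = A, cache = list(msg = msg, cnt = cnt))
  }
}

agg_backward <- function(dA, Z, src, dst, fw, beta, aggregator) {
  n <- nrow(Z)
  dZ <- matrix(0, n, ncol(Z))
  dbeta <- 0
  if (length(src) == 0) return(list(dZ = dZ, dbeta = dbeta))
  msg <- fw$cache$msg
  dA_e <- dA[dst, , drop = FALSE]
  if (aggregator == "softmax") {
    s <- fw$cache$s
    A_e <- fw$A[dst, , drop = FALSE]
    dmsg <- s * dA_e * (1 + beta * (msg - A_e))
    dbeta <- sum(s * dA_e * msg * (msg - A_e))
  } else {
    dmsg <- dA_e / fw$cache$cnt[dst]
  }
  dmsg <- dmsg * (Z[src, , drop = FALSE] > 0)
  dZ <- dZ + scatter_rowsum(dmsg, src, n)
  list(dZ = dZ, dbeta = dbeta)
}

bn_forward <- function(X, gamma, delta, run, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training && nrow(X) > 1) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, inv, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, delta, `+`)
  list(Y = Y, xhat = xhat, inv = inv, run = run, training = training)
}

bn_backward <- function(dY, fw, gamma) {
  dgamma <- colSums(dY * fw$xhat)
  ddelta <- colSums(dY)
  if (fw$training && nrow(dY) > 1) {
    n <- nrow(dY)
    t1 <- sweep(dY, 2, colMeans(dY))
    t2 <- sweep(fw$xhat, 2, colMeans(dY * fw$xhat), `*`)
    dX <- sweep(t1 - t2, 2, gamma * fw$inv, `*`)
  } else {
    dX <- sweep(dY, 2, gamma * fw$inv, `*`)
  }
  list(dX = dX, dgamma = dgamma, ddelta = ddelta)
}

conv_forward <- function(X, src, dst, P, l, model, training) {
  W <- P[[paste0("W", l)]]; b <- P[[paste0("b", l)]]
  U <- P[[paste0("U", l)]]; cc <- P[[paste0("c", l)]]
  Z <- sweep(X %*% W, 2, b, `+`)
  ag <- agg_forward(Z, src, dst, nrow(X), P[[paste0("beta", l)]],
                    model$cfg$aggregator)
  S <- Z + ag$A
  Tm <- sweep(S %*% U, 2, cc, `+`)
  bn <- bn_forward(Tm, P[[paste0("g", l)]], P[[paste0("d", l)]],
                   model$running[[paste0("bn", l)]], training)
  H <- pmax(bn$Y, 0)
  list(H = H, cache = list(X = X, Z = Z, ag = ag, S = S, bn = bn))
}

conv_backward <- function(dH, cache, src, dst, P, l, model) {
  relu_mask <- cache$bn$Y > 0
  bnb <- bn_backward(dH * relu_mask, cache$bn, P[[paste0("g", l)]])
  dT <- bnb$dX
  dU <- crossprod(cache$S, dT)
  dc <- colSums(dT)
  dS <- dT %*% t(P[[paste0("U", l)]])
  agb <- agg_backward(dS, cache$Z, src, dst, cache$ag,
                      P[[paste0("beta", l)]], model$cfg$aggregator)
  dZ <- dS + agb$dZ
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(P[[paste0("W", l)]])
  grads <- list(dW, db, dU, dc, agb$dbeta, bnb$dgamma, bnb$ddelta)
  names(grads) <- paste0(c("W", "b", "U", "c", "beta", "g", "d"), l)
  list(dX = dX, grads = grads)
}

pool_forward <- function(H, node_split) {
  h <- ncol(H)
  g <- length(node_split)
  P <- matrix(0, g, 2 * h)
  argmax <- vector("list", g)
  for (i in seq_len(g)) {
    idx <- node_split[[i]]
    M <- H[idx, , drop = FALSE]
    am <- max.col(t(M), ties.method = "first")
    argmax[[i]] <- idx[am]
    P[i, ] <- c(M[cbind(am, seq_len(h))], colMeans(M))
  }
  list(P = P, argmax = argmax)
}

pool_backward <- function(dP, fw, node_split, n, h) {
  dH <- matrix(0, n, h)
  for (i in seq_along(node_split)) {
    idx <- node_split[[i]]
    am <- fw$argmax[[i]]
    dH[cbind(am, seq_len(h))] <- dH[cbind(am, seq_len(h))] + dP[i, seq_len(h)]
    dH[idx, ] <- dH[idx, ] +
      matrix(dP[i, h + seq_len(h)] / length(idx), length(idx), h, byrow = TRUE)
  }
  dH
}

forward_gnn <- function(model, graphs, training = FALSE, dropout_mask = NULL) {
  P <- model$params
  b <- collate_batch(graphs)
  c1 <- conv_forward(b$X, b$src, b$dst, P, 1L, model, training)
  c2 <- conv_forward(c1$H, b$src, b$dst, P, 2L, model, training)
  Hjk <- cbind(c1$H, c2$H)
  pl <- pool_forward(Hjk, b$node_split)
  S3 <- sweep(pl$P %*% P$W3, 2, P$b3, `+`)
  bn3 <- bn_forward(S3, P$g3, P$d3, model$running$bn3, training)
  R <- pmax(bn3$Y, 0)
  if (training && model$cfg$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        runif(length(R)) >= model$cfg$dropout_rate, nrow(R), ncol(R)) /
        (1 - model$cfg$dropout_rate)
    }
    D <- R * dropout_mask
  } else {
    D <- R
    dropout_mask <- NULL
  }
  logits <- sweep(D %*% P$W4, 2, P$b4, `+`)
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  probs <- el / rowSums(el)
  list(probs = probs, cache = list(batch = b, c1 = c1, c2 = c2, Hjk = Hjk,
                                   pl = pl, bn3 = bn3, R = R, D = D,
                                   mask = dropout_mask),
       running = list(bn1 = c1$cache$bn$run, bn2 = c2$cache$bn$run,
                      bn3 = bn3$run))
}

backward_gnn <- function(model, fw, y, class_weights) {
  P <- model$params
  cache <- fw$cache
  b <- cache$batch
  g <- b$g
  w <- class_weights[y + 1L]
  onehot <- matrix(0, g, 2)
  onehot[cbind(seq_len(g), y + 1L)] <- 1
  dlogits <- (fw$probs - onehot) * (w / sum(w))
  grads <- list(
    W4 = crossprod(cache$D, dlogits),
    b4 = colSums(dlogits)
  )
  dD <- dlogits %*% t(P$W4)
  dR <- if (!is.null(cache$mask)) dD * cache$mask else dD
  dBn3 <- dR * (cache$bn3$Y > 0)
  bnb <- bn_backward(dBn3, cache$bn3, P$g3)
  grads$g3 <- bnb$dgamma; grads$d3 <- bnb$ddelta
  dS3 <- bnb$dX
  grads$W3 <- crossprod(cache$pl$P, dS3)
  grads$b3 <- colSums(dS3)
  dPool <- dS3 %*% t(P$W3)
  h2 <- ncol(cache$Hjk)
  dHjk <- pool_backward(dPool, cache$pl, b$node_split, b$n, h2)
  h <- h2 / 2
  dH1 <- dHjk[, seq_len(h), drop = FALSE]
  dH2 <- dHjk[, h + seq_len(h), drop = FALSE]
  cb2 <- conv_backward(dH2, cache$c2$cache, b$src, b$dst, P, 2L, model)
  dH1 <- dH1 + cb2$dX
  cb1 <- conv_backward(dH1, cache$c1$cache, b$src, b$dst, P, 1L, model)
  c(grads, cb2$grads, cb1$grads)
}

adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W1", "U1", "W2", "U2", "W3", "W4")
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nm %in% decayed) {
      upd <- upd + weight_decay * params[[nm]]  # decoupled (AdamW-style)
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Train the GNN
#'
#' Minibatch Adam on (optionally class-weighted) cross-entropy for a fixed
#' number of epochs; no early stopping. Deterministic given the training
#' seed. The per-epoch mean loss is recorded in the returned model's
#' `history`.
#'
#' @param model a [build_model()] result.
#' @param graphs list of [as_gnn_graph()] inputs.
#' @param labels optional 0/1 or `"synergy"`/`"antagonism"` vector; default
#'   taken from the graphs.
#' @param cfg a [train_config()].
#' @return the trained `synergnet_model` (with `history` data.frame).
#' @export
train_gnn <- function(model, graphs, labels = NULL, cfg = train_config()) {
  if (length(graphs) == 0) stop("empty training set")
  if (is.null(labels)) labels <- vapply(graphs, `[[`, 0L, "y")
  y <- label_to_binary(labels)
  if (anyNA(y)) stop("all training graphs need labels")
  n <- length(graphs)
  cw <- if (cfg$class_weighting) {
    counts <- pmax(tabulate(y + 1L, 2L), 1L)
    n / (2 * counts)
  } else c(1, 1)
  state <- list(m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  losses <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    t <- 0
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0; ep_w <- 0
      for (s in batch_starts) {
        take <- ord[s:min(s + cfg$batch_size - 1L, n)]
        if (length(take) < 2) next  # batch norm needs >= 2 graphs
        fw <- forward_gnn(model, graphs[take], training = TRUE)
        model$running <- fw$running
        yb <- y[take]
        wb <- cw[yb + 1L]
        pi <- fw$probs[cbind(seq_along(take), yb + 1L)]
        loss <- -sum(wb * log(pmax(pi, 1e-12))) / sum(wb)
        grads <- backward_gnn(model, fw, yb, cw)
        t <- t + 1
        st <- adam_step(model$params, grads, state, cfg$learning_rate, t,
                        weight_decay = cfg$weight_decay)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + loss * length(take)
        ep_w <- ep_w + length(take)
      }
      losses[ep] <- ep_loss / ep_w
      if (cfg$verbose > 0 && ep %% cfg$verbose == 0) {
        message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
      }
    }
  })
  model$trained <- TRUE
  model$train_seed <- cfg$seed
  model$history <- data.frame(epoch = seq_len(cfg$epochs), loss = losses)
  model
}

#' Predict synergy probabilities for a batch of graphs
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' dropout). Output order follows input order; the positive class is
#' synergy.
#'
#' @param model a `synergnet_model`.
#' @param graphs list of `gnn_graph`s.
#' @param batch_size evaluation minibatch size.
#' @return a list of class `prediction_output`: `prob` (n x 2 matrix,
#'   columns antagonism/synergy), `score` (synergy probability), `label`
#'   (0/1 at threshold 0.5).
#' @export
predict_gnn <- function(model, graphs, batch_size = 64L) {
  if (length(graphs) == 0) {
    return(structure(list(prob = matrix(0, 0, 2), score = numeric(0),
                          label = integer(0)), class = "prediction_output"))
  }
  probs <- matrix(0, length(graphs), 2,
                  dimnames = list(NULL, c("antagonism", "synergy")))
  for (s in seq(1, length(graphs), by = batch_size)) {
    take <- s:min(s + batch_size - 1L, length(graphs))
    fw <- forward_gnn(model, graphs[take], training = FALSE)
    probs[take, ] <- fw$probs
  }
  structure(list(prob = probs, score = probs[, 2],
                 label = as.integer(probs[, 2] >= 0.5)),
            class = "prediction_output")
}

#' @export
print.synergnet_model <- function(x, ...) {
  cat(sprintf(
    "synergnet_model: in %d | hidden %d | head %d | %s aggregation | %s\n",
    x$cfg$in_dim, x$cfg$hidden_dim, x$cfg$head_hidden, x$cfg$aggregator,
    if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %d trainable parameters\n", count_params(x)))
  invisible(x)
}

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint records every trainable parameter, the batch-norm running
#' statistics, the full model configuration, the initialization seed and
#' (when trained) the training seed and loss history, so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `synergnet_model`.
#' @param path checkpoint file path.
#' @return invisibly `model`; `read_model()` returns the model.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    running = model$running,
    cfg = unclass(model$cfg),
    seed = model$seed,
    train_seed = model$train_seed,
    trained = model$trained,
    history = model$history
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(j$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else as.numeric(p$data)
  })
  cfg <- do.call(model_config, as.list(j$cfg)[names(formals(model_config))])
  structure(list(params = params,
                 running = lapply(j$running, function(r)
                   list(mean = as.numeric(r$mean), var = as.numeric(r$var))),
                 cfg = cfg, seed = j$seed,
                 train_seed = j$train_seed,
                 trained = isTRUE(j$trained),
                 history = j$history),
            class = "synergnet_model")
}

#' Classifier spec wrapping the GNN for cross-validation
#'
#' @param graph_store named list instance id -> `reduced_graph` or
#'   `gnn_graph` covering every instance that can appear in training or
#'   testing (see [build_instance_graphs()]).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @return a spec `list(fit, predict)` for [cross_validate()].
#' @export
gnn_classifier <- function(graph_store, model_cfg = model_config(),
                           train_cfg = train_config()) {
  to_g <- function(x, label = NULL) {
    if (inherits(x, "gnn_graph")) x else as_gnn_graph(x, label)
  }
  lookup <- function(tab) {
    missing <- setdiff(tab$id, names(graph_store))
    if (length(missing)) stop("no graph for instance ", missing[1])
    lapply(seq_len(nrow(tab)),
           function(i) to_g(graph_store[[tab$id[i]]], tab$label[i]))
  }
  list(
    fit = function(train_tab) {
      g <- lookup(train_tab)
      model <- build_model(model_cfg, seed = train_cfg$seed)
      train_gnn(model, g, labels = train_tab$label, cfg = train_cfg)
    },
    predict = function(model, tab) {
      predict_gnn(model, lookup(tab))$score
    }
  )
}
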