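# Cheap structural and contract tests for the GNN; the expensive
# planted-signal learnability checks live in test-acceptance.R.

tiny_graphs <- function(n = 8, seed = 2) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nn <- sample(3:7, 1)
    g <- rand_gnp(nn, 0.5, seed = 50 + i)
    structure(list(x = matrix(rnorm(nn * 218), nn, 218),
                   edge_index = {
                     idx <- stats::setNames(seq_len(nn), g$nodes)
                     if (nrow(g$edges)) rbind(c(idx[g$edges[, 1]],
                                                idx[g$edges[, 2]]),
                                              c(idx[g$edges[, 2]],
                                                idx[g$edges[, 1]]))
                     else matrix(integer(0), 2)
                   },
                   n = nn, y = sample(0:1, 1)), class = "gnn_graph")
  })
}

test_that("forward produces normalized probabilities of the right shape", {
  m <- build_model(model_config(hidden_dim = 8, head_hidden = 8), seed = 1)
  gs <- tiny_graphs(5)
  p <- predict_gnn(m, gs)
  expect_equal(dim(p$prob), c(5L, 2L))
  expect_equal(rowSums(p$prob), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  expect_identical(p$label, as.integer(p$score >= 0.5))
  # empty input
  p0 <- predict_gnn(m, list())
  expect_equal(length(p0$score), 0L)
  # single-node graph (max = mean = that node's embedding)
  solo <- structure(list(x = matrix(rnorm(218), 1), n = 1L,
                         edge_index = matrix(integer(0), 2), y = 1L),
                    class = "gnn_graph")
  ps <- predict_gnn(m, list(solo))
  expect_equal(sum(ps$prob), 1, tolerance = 1e-12)
})

test_that("graph-level output is invariant to node permutation", {
  m <- build_model(model_config(hidden_dim = 8, head_hidden = 8), seed = 3)
  g <- tiny_graphs(1, seed = 9)[[1]]
  p1 <- predict_gnn(m, list(g))$prob
  set.seed(1)
  for (i in 1:5) {
    perm <- sample.int(g$n)
    inv <- order(perm)
    g2 <- g
    g2$x <- g$x[perm, , drop = FALSE]
    g2$edge_index <- matrix(inv[g$edge_index], 2)
    p2 <- predict_gnn(m, list(g2))$prob
    expect_equal(p2, p1, tolerance = 1e-8)
  }
})

test_that("parameter count matches a hand tally", {
  h <- 8; p <- 4
  m <- build_model(model_config(hidden_dim = h, head_hidden = p), seed = 1)
  tally <-
    (218 * h + h) + (h * h + h) + 1 + (h + h) +   # conv1 + bn1
    (h * h + h) + (h * h + h) + 1 + (h + h) +     # conv2 + bn2
    (4 * h * p + p) + (p + p) +                   # head linear 1 + bn3
    (p * 2 + 2)                                   # head linear 2
  expect_identical(count_params(m), as.integer(tally))
})

test_that("readout width doubles the JK width (max and mean concatenated)", {
  h <- 8
  m <- build_model(model_config(hidden_dim = h, head_hidden = 4), seed = 1)
  # W3 input dimension is 2 blocks (max, mean) of the 2h-wide JK concat
  expect_equal(nrow(m$params$W3), 2 * (2 * h))
})

test_that("training reduces loss and is reproducible under a seed", {
  set.seed(33)
  gs <- tiny_graphs(50, seed = 7)
  # plant an easy signal so optimization has something to fit
  for (i in seq_along(gs)) {
    gs[[i]]$y <- as.integer(mean(gs[[i]]$x[, 1]) > 0)
  }
  cfg <- model_config(hidden_dim = 8, head_hidden = 8)
  tc <- train_config(epochs = 30, seed = 5, batch_size = 16)
  m1 <- train_gnn(build_model(cfg, seed = 5), gs, cfg = tc)
  expect_lt(mean(tail(m1$history$loss, 5)), m1$history$loss[1])
  m2 <- train_gnn(build_model(cfg, seed = 5), gs, cfg = tc)
  expect_identical(predict_gnn(m1, gs)$score, predict_gnn(m2, gs)$score)
  # untrained model with frozen seed is reproducible too
  u1 <- predict_gnn(build_model(cfg, seed = 9), gs)$score
  u2 <- predict_gnn(build_model(cfg, seed = 9), gs)$score
  expect_identical(u1, u2)
  expect_error(train_gnn(build_model(cfg), list()), "empty")
})

test_that("as_gnn_graph carries reduced-graph features and labels", {
  fg <- toy_contraction_graph()
  rg <- reduce_graph(fg)
  g <- as_gnn_graph(rg)
  expect_equal(nrow(g$x), 6L)
  expect_equal(ncol(g$x), 218L)
  expect_equal(g$y, 1L)  # "synergy"
  expect_equal(ncol(g$edge_index), 2 * nrow(rg$edges))
  # feature-length mismatch is rejected at forward time
  m <- build_model(model_config(hidden_dim = 4, head_hidden = 4,
                                in_dim = 10L), seed = 1)
  expect_error(predict_gnn(m, list(g)))
})

test_that("model checkpoints round-trip with identical predictions", {
  gs <- tiny_graphs(6, seed = 21)
  m <- train_gnn(build_model(model_config(hidden_dim = 6, head_hidden = 4),
                             seed = 2),
                 gs, labels = vapply(gs, `[[`, 0L, "y"),
                 cfg = train_config(epochs = 5, seed = 3, batch_size = 3))
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_gnn(m2, gs)$score, predict_gnn(m, gs)$score,
               tolerance = 1e-12)
  expect_identical(m2$trained, TRUE)
  expect_equal(m2$cfg$hidden_dim, 6)
})

test_that("mean aggregation variant also runs", {
  m <- build_model(model_config(hidden_dim = 8, head_hidden = 8,
                                aggregator = "mean"), seed = 2)
  p <- predict_gnn(m, tiny_graphs(3))
  expect_equal(rowSums(p$prob), rep(1, 3), tolerance = 1e-12)
})
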