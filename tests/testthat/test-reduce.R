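test_that("pruning implements the three removal rules", {
  fg <- toy_contraction_graph()
  pe <- prune_edges(fg)
  keys <- paste(pe[, 1], pe[, 2])
  expect_setequal(keys, c("d e", "f i", "g h"))
  # druggable--non-druggable edge removed
  expect_false("a b" %in% keys)
  # edges at the target node removed
  expect_false(any(grepl("c", keys)))
  # differing expression removed (e: +1, f: -1)
  expect_false("e f" %in% keys)
})

test_that("the 9-node worked example contracts to the forced partition", {
  fg <- toy_contraction_graph()
  part <- contract(fg, prune_edges(fg))
  expect_equal(part$members,
               list("a", "b", "c", c("d", "e"), c("f", "i"), c("g", "h")))
  rg <- reduce_graph(fg)
  expect_equal(length(rg$nodes), 6L)
  expect_setequal(rg$nodes, c("a", "b", "c", "d+e", "f+i", "g+h"))
  # restored connectivity is the quotient of the original adjacency
  expect_setequal(paste(rg$edges[, 1], rg$edges[, 2]),
                  c("a b", "b c", "c d+e", "d+e f+i", "f+i g+h", "a g+h",
                    "a d+e"))
})

test_that("contraction is component closure and order-independent", {
  fg <- toy_contraction_graph()
  # chain transitivity
  chain <- rbind(c("d", "e"), c("e", "f"))
  part <- contract(fg, chain)
  expect_true(any(vapply(part$members, function(m)
    setequal(m, c("d", "e", "f")), TRUE)))
  # no persisting edges -> identity partition
  id_part <- contract(fg, fg$topology$edges[0, , drop = FALSE])
  expect_equal(length(id_part$members), 9L)
  # shuffled edge order gives the identical partition
  pe <- prune_edges(fg)
  set.seed(1)
  for (i in 1:5) {
    perm <- pe[sample.int(nrow(pe)), , drop = FALSE]
    expect_identical(contract(fg, perm)$members, contract(fg, pe)$members)
  }
})

test_that("feature merging follows the blockwise policy", {
  fg <- toy_contraction_graph()
  part <- contract(fg, prune_edges(fg))
  bl <- feature_blocks()
  X <- fg$features
  X[, bl$go] <- matrix(rnorm(nrow(X) * 200), nrow(X))
  M <- merge_features(part, X)
  # singleton unchanged
  expect_equal(M["a", ], unname(X["a", ]))
  # indicator max and GO mean on the d+e merge, against direct arithmetic
  expect_equal(M["d+e", bl$mutation],
               pmax(X["d", bl$mutation], X["e", bl$mutation]))
  expect_equal(M["d+e", bl$go], (X["d", bl$go] + X["e", bl$go]) / 2)
  expect_equal(unname(M["d+e", bl$expression]), 1)
  # mutation union: plant disjoint indicators and check the max rule
  X2 <- X
  X2["d", bl$mutation] <- c(1, rep(0, 12))
  X2["e", bl$mutation] <- c(0, 1, rep(0, 11))
  M2 <- merge_features(part, X2)
  expect_equal(M2["d+e", bl$mutation], c(1, 1, rep(0, 11)))
})

test_that("reduced graphs are exact quotients (oracle on random graphs)", {
  b <- small_bundle()
  set.seed(4)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    g <- rand_gnp(n, runif(1, 0.05, 0.15), seed = 100 + rep)
    prof <- b$profiles[[sample(length(b$profiles), 1)]]
    # remap a random expression pattern onto this graph's nodes
    expr <- stats::setNames(sample(c(-1, 0, 1), n, replace = TRUE,
                                   prob = c(0.2, 0.6, 0.2)), g$nodes)
    prof2 <- cell_line_profile("X", expression = expr[expr != 0])
    da <- drug_record("A", associations = stats::setNames(
      runif(2, 150, 999), sample(g$nodes, 2)))
    db <- drug_record("B", associations = stats::setNames(
      runif(2, 150, 999), sample(g$nodes, 2)))
    fg <- build_featured_graph(g, prof2, da, db)
    rg <- reduce_graph(fg)
    # oracle quotient on membership labels
    memb <- rg$partition$membership
    expect_setequal(
      paste(pmin(rg$edges[, 1], rg$edges[, 2]),
            pmax(rg$edges[, 1], rg$edges[, 2])),
      {
        keys <- oracle_quotient(g$edges, memb)
        sid <- rg$partition$super_ids
        vapply(strsplit(keys, " "), function(k) {
          s <- sort(sid[as.integer(k)]); paste(s[1], s[2])
        }, "")
      })
    # invariants: homogeneity, target singletons, monotone size
    for (m in rg$partition$members) {
      expect_length(unique(g$druggable[m]), 1L)
      expect_length(unique(expr[m]), 1L)
    }
    for (t in union(fg$target_nodes_a, fg$target_nodes_b)) {
      expect_true(list(t) %in% rg$partition$members)
    }
    expect_lte(length(rg$nodes), n)
    expect_lte(nrow(rg$edges), nrow(g$edges))
    # connectivity quotient: component count preserved
    ig1 <- igraph::graph_from_data_frame(as.data.frame(g$edges),
      directed = FALSE, vertices = data.frame(name = g$nodes))
    ig2 <- igraph::graph_from_data_frame(as.data.frame(rg$edges),
      directed = FALSE, vertices = data.frame(name = rg$nodes))
    expect_equal(igraph::components(ig2)$no, igraph::components(ig1)$no)
  }
})

test_that("degenerate cases: unique expression values block reduction", {
  nodes <- letters[1:5]
  g <- ppi_network(nodes, rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                                c("d", "e")),
                   druggable = rep(TRUE, 5))
  # all-different expression impossible with 3 levels on a path; instead make
  # every adjacent pair differ
  expr <- c(a = -1, b = 0, c = 1, d = 0, e = 1)
  prof <- cell_line_profile("X", expression = expr[expr != 0])
  fg <- build_featured_graph(g, prof, drug_record("A"), drug_record("B"))
  rg <- reduce_graph(fg)
  expect_equal(length(rg$nodes), 5L)
  expect_equal(nrow(rg$edges), 4L)
})

test_that("reduced graphs serialize round-trip through JSON", {
  fg <- toy_contraction_graph()
  rg <- reduce_graph(fg)
  f <- tempfile(fileext = ".json")
  write_reduced_graph(rg, f)
  rg2 <- read_reduced_graph(f)
  expect_identical(rg2$nodes, rg$nodes)
  expect_identical(unname(rg2$edges), unname(rg$edges))
  expect_equal(unname(rg2$features), unname(rg$features))
  expect_identical(unname(rg2$druggable), unname(rg$druggable))
})

test_that("synthetic-scale reduction shrinks node count substantially", {
  b <- small_bundle()
  syn <- b$synergy[1:5]
  store <- build_instance_graphs(b, syn)
  sizes <- vapply(store, function(g) length(g$nodes), 0L)
  expect_true(all(sizes < length(b$ppi$nodes)))
  expect_true(mean(sizes) < 0.75 * length(b$ppi$nodes))
})
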