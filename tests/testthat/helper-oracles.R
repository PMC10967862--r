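# Independent oracles used by the suite. These deliberately avoid the code
# paths (and the igraph backend) they are checking.

# all-pairs BFS eccentricities on the largest connected component
oracle_diameter <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(start) {
    d <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    d[start] <- 0L
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.na(d[v])) {
            d[v] <- d[u] + 1L
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    d
  }
  # largest component via repeated BFS
  unseen <- nodes
  best_comp <- character(0)
  while (length(unseen) > 0) {
    d <- bfs(unseen[1])
    comp <- names(d)[!is.na(d)]
    if (length(comp) > length(best_comp)) best_comp <- comp
    unseen <- setdiff(unseen, comp)
  }
  max(vapply(best_comp, function(s) {
    d <- bfs(s)
    max(d[best_comp], na.rm = TRUE)
  }, 0L))
}

# quotient-graph edge set by relabel-and-dedupe
oracle_quotient <- function(edges, membership) {
  if (nrow(edges) == 0) return(character(0))
  a <- membership[edges[, 1]]
  b <- membership[edges[, 2]]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(pmin(a, b), pmax(a, b))
  sort(unique(key))
}

# confusion-matrix metrics by explicit counting; AUC by pairwise comparison
oracle_metrics <- function(y, s, thr = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(y)) {
    if (s[i] >= thr) {
      if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
    } else {
      if (y[i] == 1) fn <- fn + 1 else tn <- tn + 1
    }
  }
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  num <- 0; den <- 0
  for (i in which(y == 1)) {
    for (j in which(y == 0)) {
      den <- den + 1
      if (s[i] > s[j]) num <- num + 1
      if (s[i] == s[j]) num <- num + 0.5
    }
  }
  mcc_d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(auc = if (den > 0) num / den else NA_real_,
       bac = (tpr + tnr) / 2,
       ppv = if (tp + fp > 0) tp / (tp + fp) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
       mcc = if (mcc_d > 0) (tp * tn - fp * fn) / mcc_d else 0)
}

# Erdos-Renyi test graph with random druggability
rand_gnp <- function(n, p, seed, druggable_frac = 0.5) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  take <- runif(nrow(pairs)) < p
  ppi_network(nodes, pairs[take, , drop = FALSE],
              druggable = runif(n) < druggable_frac)
}

# the 9-node worked example of constrained contraction:
# druggable b, c, g, h (c the sole target); the pruning rules force the
# partition {a},{b},{c},{d,e},{f,i},{g,h}
toy_contraction_graph <- function() {
  nodes <- c("a", "b", "c", "d", "e", "f", "g", "h", "i")
  druggable <- nodes %in% c("b", "c", "g", "h")
  edges <- rbind(
    c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "f"),
    c("f", "i"), c("g", "i"), c("g", "h"), c("a", "h"), c("a", "d"))
  ppi <- ppi_network(nodes, edges, druggable = druggable)
  expr <- c(a = 0, b = 1, c = 0, d = 1, e = 1, f = -1, g = 0, h = 0, i = -1)
  profile <- cell_line_profile("TOY", expression = expr[expr != 0])
  da <- drug_record("DA", associations = c(c = 800))
  db <- drug_record("DB", associations = c(c = 500))
  build_featured_graph(ppi, profile, da, db, label = "synergy")
}

# small shared synthetic bundle (computed once per test run)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_proteins = 80L, n_drugs = 24L, n_families = 6L,
                          n_cell_lines = 4L, n_pairs = 120L, seed = 11L)
      cache <<- make_dataset(cfg)
    }
    cache
  }
})
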