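# Knowledge-based graph reduction through constrained edge contraction.
#
# Nodes similar in their potential drug interaction (druggability class,
# non-target) and in their activity level (identical trinary expression) are
# merged: edges violating any of those similarity rules are pruned, the
# persisting edges are contracted (connected-component closure, which is the
# canonical, order-independent result of pairwise contraction), merged-node
# features are combined blockwise, and finally all original edges are
# restored on the quotient graph.

#' Persisting edges of the contraction step
#'
#' Returns the edges of a featured graph that survive the pruning rules and
#' will therefore be contracted: an edge (u, v) persists iff u and v share
#' the druggability class, neither is a target node of either instance drug,
#' and both have the same trinary expression value.
#'
#' @param g a [build_featured_graph()] result.
#' @return a two-column character matrix (possibly zero rows).
#' @export
prune_edges <- function(g) {
  ed <- g$topology$edges
  if (nrow(ed) == 0) return(ed)
  drug <- g$topology$druggable
  expr <- g$features[, feature_blocks()$expression]
  targets <- union(g$target_nodes_a, g$target_nodes_b)
  u <- ed[, 1]; v <- ed[, 2]
  keep <- (drug[u] == drug[v]) &
    !(u %in% targets) & !(v %in% targets) &
    (expr[u] == expr[v])
  ed[keep, , drop = FALSE]
}

#' Contract persisting edges into a merge partition
#'
#' Super-nodes are the connected components of the subgraph induced by the
#' persisting edges; nodes untouched by any persisting edge stay singletons.
#' Component closure makes the result invariant to edge order.
#'
#' @param g a featured graph.
#' @param persisting_edges two-column character matrix, a subset of the
#'   graph's edges (typically from [prune_edges()]).
#' @return an object of class `merge_partition`: `membership` (named integer
#'   vector original node -> super-node index), `members` (list of character
#'   vectors), `super_ids` (character ids, member names joined by `+`).
#' @export
contract <- function(g, persisting_edges) {
  nodes <- g$topology$nodes
  memb <- seq_along(nodes)
  names(memb) <- nodes
  if (nrow(persisting_edges) > 0) {
    sub <- igraph::graph_from_data_frame(
      as.data.frame(persisting_edges, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    memb <- igraph::components(sub)$membership[nodes]
  }
  # renumber components canonically by their lexicographically first member
  first <- tapply(nodes, memb, function(m) sort(m)[1])
  ord <- order(first)
  remap <- integer(length(first))
  remap[as.integer(names(first))[ord]] <- seq_along(first)
  memb <- remap[memb]
  names(memb) <- nodes
  members <- split(nodes, memb)
  members <- lapply(members, sort)
  names(members) <- NULL
  structure(list(
    membership = memb,
    members = members,
    super_ids = vapply(members, paste, "", collapse = "+")
  ), class = "merge_partition")
}

#' Combine member features of each super-node
#'
#' Blockwise merge policy (each configurable): expression keeps the shared
#' member value (guaranteed identical by the pruning rules); CNV one-hot and
#' mutation indicators take the element-wise maximum (union of alterations);
#' the association score takes the maximum; the GO embedding block takes the
#' element-wise mean (average functional embedding).
#'
#' @param partition a [contract()] result.
#' @param node_features numeric matrix, rownames = original nodes.
#' @param policy named list with entries `indicators` and `go`, each
#'   `"max"` or `"mean"`; defaults `list(indicators = "max", go = "mean")`.
#' @return numeric matrix with one row per super-node (rownames =
#'   `partition$super_ids`).
#' @export
merge_features <- function(partition, node_features,
                           policy = list(indicators = "max", go = "mean")) {
  bl <- feature_blocks()
  k <- length(partition$members)
  out <- matrix(0, nrow = k, ncol = ncol(node_features),
                dimnames = list(partition$super_ids, NULL))
  agg <- function(M, how) {
    if (nrow(M) == 1) return(M[1, ])
    switch(how, max = apply(M, 2, max), mean = colMeans(M),
           stop("unknown merge policy: ", how))
  }
  ind_cols <- c(bl$cnv, bl$mutation, bl$association)
  for (i in seq_len(k)) {
    M <- node_features[partition$members[[i]], , drop = FALSE]
    ex <- M[, bl$expression]
    if (length(unique(ex)) != 1) {
      stop("internal error: super-node members disagree on expression")
    }
    out[i, bl$expression] <- ex[1]
    out[i, ind_cols] <- agg(M[, ind_cols, drop = FALSE], policy$indicators)
    out[i, bl$go] <- agg(M[, bl$go, drop = FALSE], policy$go)
  }
  out
}

#' Restore original connectivity on the quotient graph
#'
#' Every original edge (u, v) whose endpoints fall in different super-nodes
#' induces the edge (S(u), S(v)) in the reduced graph; duplicates are
#' collapsed and would-be self-loops dropped, yielding a simple quotient
#' graph. With `edge_weights = TRUE` the multiplicity of collapsed parallel
#' edges is recorded (off by default).
#'
#' @param partition a [contract()] result.
#' @param original the source featured graph.
#' @param features optional pre-merged super-node feature matrix (computed
#'   via [merge_features()] if NULL).
#' @param edge_weights logical; record parallel-edge multiplicities.
#' @return an object of class `reduced_graph`: `nodes`, `edges`, `features`,
#'   `druggable`, `partition`, `weights` (optional), `instance`,
#'   `provenance`.
#' @export
restore_edges <- function(partition, original, features = NULL,
                          edge_weights = FALSE) {
  if (is.null(features)) {
    features <- merge_features(partition, original$features)
  }
  sid <- partition$super_ids
  ed <- original$topology$edges
  weights <- NULL
  if (nrow(ed) > 0) {
    su <- sid[partition$membership[ed[, 1]]]
    sv <- sid[partition$membership[ed[, 2]]]
    keep <- su != sv
    su <- su[keep]; sv <- sv[keep]
    swap <- su > sv
    tmp <- su[swap]; su[swap] <- sv[swap]; sv[swap] <- tmp
    key <- paste(su, sv, sep = "\r")
    if (edge_weights) {
      tab <- table(key)
      uk <- names(tab)
      parts <- strsplit(uk, "\r", fixed = TRUE)
      red <- cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
      weights <- as.integer(tab)
      ord <- order(red[, 1], red[, 2])
      red <- red[ord, , drop = FALSE]; weights <- weights[ord]
    } else {
      dup <- duplicated(key)
      red <- cbind(su[!dup], sv[!dup])
      red <- red[order(red[, 1], red[, 2]), , drop = FALSE]
    }
  } else {
    red <- matrix(character(0), ncol = 2)
  }
  drug <- vapply(partition$members,
                 function(m) original$topology$druggable[m[1]], logical(1))
  names(drug) <- sid
  structure(list(
    nodes = sid,
    edges = red,
    features = features,
    druggable = drug,
    partition = partition,
    weights = weights,
    instance = original$instance,
    provenance = paste(original$instance$drug_a, original$instance$drug_b,
                       original$instance$cell_line, sep = "|")
  ), class = c("reduced_graph", "ppi_network"))
}

#' Reduce a featured graph by constrained edge contraction
#'
#' Composition of [prune_edges()], [contract()], [merge_features()] and
#' [restore_edges()].
#'
#' @param g a featured graph.
#' @param policy feature-merge policy, see [merge_features()].
#' @param edge_weights see [restore_edges()].
#' @return a `reduced_graph`.
#' @export
reduce_graph <- function(g, policy = list(indicators = "max", go = "mean"),
                         edge_weights = FALSE) {
  part <- contract(g, prune_edges(g))
  restore_edges(part, g, merge_features(part, g$features, policy),
                edge_weights = edge_weights)
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat(sprintf("reduced_graph: %d super-nodes, %d edges (from %s)\n",
              length(x$nodes), nrow(x$edges), x$provenance))
  invisible(x)
}

#' Serialize / deserialize a reduced graph as JSON
#' @param g a `reduced_graph`.
#' @param path output (input) file path.
#' @return invisibly `g`; `read_reduced_graph()` returns the object.
#' @export
write_reduced_graph <- function(g, path) {
  jsonlite::write_json(list(
    nodes = g$nodes,
    members = g$partition$members,
    edges = if (nrow(g$edges)) unname(apply(g$edges, 1, as.list)) else list(),
    features = unname(lapply(seq_len(nrow(g$features)),
                             function(i) g$features[i, ])),
    druggable = unname(g$druggable),
    instance = g$instance,
    provenance = g$provenance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(g)
}

#' @rdname write_reduced_graph
#' @export
read_reduced_graph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(j$members, as.character)
  nodes <- as.character(j$nodes)
  memb <- integer(0)
  for (i in seq_along(members)) {
    m <- stats::setNames(rep(i, length(members[[i]])), members[[i]])
    memb <- c(memb, m)
  }
  feats <- if (is.matrix(j$features)) j$features else
    do.call(rbind, lapply(j$features, as.numeric))
  storage.mode(feats) <- "double"
  rownames(feats) <- nodes
  ed <- if (length(j$edges)) {
    if (is.data.frame(j$edges)) j$edges <- as.matrix(j$edges)
    m <- if (is.matrix(j$edges)) j$edges else
      do.call(rbind, lapply(j$edges, function(e) unlist(e, use.names = FALSE)))
    storage.mode(m) <- "character"
    m
  } else matrix(character(0), ncol = 2)
  structure(list(
    nodes = nodes, edges = ed, features = feats,
    druggable = stats::setNames(as.logical(j$druggable), nodes),
    partition = structure(list(membership = memb, members = members,
                               super_ids = nodes), class = "merge_partition"),
    weights = NULL,
    instance = j$instance,
    provenance = j$provenance
  ), class = c("reduced_graph", "ppi_network"))
}
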