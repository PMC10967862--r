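#' @importFrom stats rbinom runif rnorm quantile sd var predict
#' @importFrom utils head tail
NULL

#' Construct a PPI network object
#'
#' A `ppi_network` is the shared topology underlying every synergy instance:
#' an undirected simple graph over protein identifiers, each node flagged as
#' druggable (a recorded target of at least one drug) or not, with optional
#' per-edge confidence scores in \[0, 1\].
#'
#' Edges are canonicalized (endpoints sorted lexicographically), deduplicated,
#' and validated: self-loops are an error and every endpoint must be a
#' declared node.
#'
#' @param nodes character vector of protein identifiers (unique).
#' @param edges two-column character matrix (or data.frame) of endpoints.
#' @param druggable logical vector parallel to `nodes` (or named by node).
#' @param confidence optional numeric vector parallel to the edge rows.
#' @return An object of class `ppi_network` with fields `nodes`, `edges`
#'   (canonical two-column character matrix), `druggable` (named logical) and
#'   `confidence` (named numeric or NULL).
#' @export
ppi_network <- function(nodes, edges, druggable = NULL, confidence = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2) stop("edges must have two columns")
    dimnames(edges) <- NULL
  }
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    missing <- setdiff(c(edges[, 1], edges[, 2]), nodes)
    if (length(missing) > 0) {
      stop("edge references unannotated node(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    swap <- edges[, 1] > edges[, 2]
    if (any(swap)) edges[swap, ] <- edges[swap, c(2, 1), drop = FALSE]
    key <- paste(edges[, 1], edges[, 2], sep = "\r")
    keep <- !duplicated(key)
    if (!is.null(confidence)) {
      if (length(confidence) != length(key)) {
        stop("confidence must be parallel to edges")
      }
      confidence <- confidence[keep]
    }
    edges <- edges[keep, , drop = FALSE]
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
    if (!is.null(confidence)) {
      confidence <- confidence[ord]
      names(confidence) <- paste(edges[, 1], edges[, 2], sep = "|")
    }
  }
  if (is.null(druggable)) {
    druggable <- rep(FALSE, length(nodes))
  } else if (!is.null(names(druggable))) {
    druggable <- unname(druggable[nodes])
    druggable[is.na(druggable)] <- FALSE
  }
  if (length(druggable) != length(nodes)) {
    stop("druggable must be parallel to nodes")
  }
  druggable <- as.logical(druggable)
  names(druggable) <- nodes
  structure(
    list(nodes = nodes, edges = edges, druggable = druggable,
         confidence = confidence),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges, %d druggable\n",
              length(x$nodes), nrow(x$edges), sum(x$druggable)))
  invisible(x)
}

#' Number of nodes / edges of a PPI network
#' @param g a `ppi_network`.
#' @return integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Read a PPI network from an edge-list TSV
#'
#' The edge list has one interaction per row,
#' `protein_a<TAB>protein_b<TAB>confidence` (confidence optional); a companion
#' node table `protein<TAB>druggable{0,1}` declares every node and its
#' druggability flag. Edges below `min_confidence` are dropped; edges are
#' canonicalized and deduplicated; isolated annotated nodes are retained.
#'
#' @param path edge-list TSV path.
#' @param nodes_path node-table TSV path.
#' @param min_confidence drop edges with confidence below this value
#'   (default 0.7, the conventional high-confidence interaction threshold).
#' @param self_loops `"error"` (default) or `"drop"` (drop with a warning).
#' @param header logical; do the files carry header rows? Default TRUE.
#' @return a [ppi_network()].
#' @export
read_ppi_network <- function(path, nodes_path, min_confidence = 0.7,
                             self_loops = c("error", "drop"), header = TRUE) {
  self_loops <- match.arg(self_loops)
  ed <- data.table::fread(path, header = header, sep = "\t",
                          colClasses = list(character = 1:2))
  if (ncol(ed) < 2) stop("malformed edge list: need >= 2 columns in ", path)
  nt <- data.table::fread(nodes_path, header = header, sep = "\t")
  if (ncol(nt) < 2) stop("malformed node table: need 2 columns in ", nodes_path)
  bad <- which(is.na(ed[[1]]) | is.na(ed[[2]]) | ed[[1]] == "" | ed[[2]] == "")
  if (length(bad) > 0) {
    stop("malformed edge row at line ", bad[1] + as.integer(header), " of ", path)
  }
  conf <- if (ncol(ed) >= 3) suppressWarnings(as.numeric(ed[[3]])) else
    rep(1, nrow(ed))
  if (anyNA(conf)) {
    stop("malformed confidence at line ",
         which(is.na(conf))[1] + as.integer(header), " of ", path)
  }
  keep <- conf >= min_confidence
  a <- ed[[1]][keep]; b <- ed[[2]][keep]; conf <- conf[keep]
  loop <- a == b
  if (any(loop)) {
    if (self_loops == "error") stop("self-loop in edge list: ", a[which(loop)[1]])
    warning(sum(loop), " self-loop(s) dropped")
    a <- a[!loop]; b <- b[!loop]; conf <- conf[!loop]
  }
  ppi_network(nodes = as.character(nt[[1]]),
              edges = cbind(a, b),
              druggable = as.logical(as.integer(nt[[2]]) != 0),
              confidence = conf)
}

#' Write a PPI network to edge-list + node-table TSVs
#' @param g a `ppi_network`.
#' @param path,nodes_path output TSV paths.
#' @return invisibly, `g`.
#' @export
write_ppi_network <- function(g, path, nodes_path) {
  conf <- if (is.null(g$confidence)) rep(1, n_edges(g)) else unname(g$confidence)
  data.table::fwrite(
    data.table::data.table(protein_a = g$edges[, 1], protein_b = g$edges[, 2],
                           confidence = conf),
    path, sep = "\t")
  data.table::fwrite(
    data.table::data.table(protein = g$nodes,
                           druggable = as.integer(g$druggable)),
    nodes_path, sep = "\t")
  invisible(g)
}

#' Average node degree
#'
#' For an undirected simple graph, the mean number of connections per node,
#' `2E/V`.
#'
#' @param g a `ppi_network` (or anything with `nodes`/`edges` fields).
#' @return a real number.
#' @export
avg_degree <- function(g) {
  if (n_nodes(g) == 0) stop("average degree undefined on an empty graph")
  2 * n_edges(g) / n_nodes(g)
}

#' Graph density
#'
#' Edges divided by the maximum possible number of edges of a simple
#' undirected graph: `2E / (V (V - 1))`.
#'
#' @inheritParams avg_degree
#' @return a real number in \[0, 1\].
#' @export
graph_density <- function(g) {
  v <- n_nodes(g)
  if (v < 2) stop("density undefined for fewer than 2 nodes")
  2 * n_edges(g) / (v * (v - 1))
}

#' Graph diameter
#'
#' Maximum shortest-path length over node pairs. A disconnected graph has no
#' finite all-pairs diameter, so the diameter is computed on the largest
#' connected component and the component count is reported via a message.
#' An edgeless graph returns 0 with a warning.
#'
#' @inheritParams avg_degree
#' @return an integer.
#' @export
graph_diameter <- function(g) {
  if (n_nodes(g) == 0) stop("diameter undefined on an empty graph")
  if (n_edges(g) == 0) {
    warning("edgeless graph: diameter reported as 0")
    return(0L)
  }
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  if (comp$no > 1) {
    message(comp$no, " connected components; diameter computed on the largest")
    giant <- which.max(comp$csize)
    ig <- igraph::induced_subgraph(ig, which(comp$membership == giant))
  }
  as.integer(igraph::diameter(ig, directed = FALSE, unconnected = FALSE))
}

#' Summary statistics of a (featured or reduced) graph
#'
#' Returns node and edge counts, average degree, density, diameter, and the
#' ratio of druggable to non-druggable nodes.
#'
#' @inheritParams avg_degree
#' @return a list of class `graph_stats` with fields `n_nodes`, `n_edges`,
#'   `avg_degree`, `density`, `diameter`, `druggable_ratio`.
#' @export
graph_stats <- function(g) {
  nd <- sum(g$druggable)
  structure(list(
    n_nodes = n_nodes(g),
    n_edges = n_edges(g),
    avg_degree = avg_degree(g),
    density = graph_density(g),
    diameter = graph_diameter(g),
    druggable_ratio = nd / (n_nodes(g) - nd)
  ), class = "graph_stats")
}

#' Average degree and density from published node/edge counts
#'
#' Evaluates the closed-form graph statistics `2E/V` and `2E/(V(V-1))`
#' directly from counts, for use with published network summaries where the
#' full edge list is not distributed.
#'
#' @param n_nodes,n_edges node and edge counts.
#' @return list with `avg_degree` and `density`.
#' @export
graph_stats_from_counts <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  list(avg_degree = 2 * n_edges / n_nodes,
       density = 2 * n_edges / (n_nodes * (n_nodes - 1)))
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "nodes %d | edges %d | avg degree %.2f | density %.5f | ",
    "diameter %d | druggable/non-druggable %.2f\n"),
    x$n_nodes, x$n_edges, x$avg_degree, x$density, x$diameter,
    x$druggable_ratio))
  invisible(x)
}
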