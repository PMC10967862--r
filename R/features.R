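# Node-feature assembly: every (drug pair, cell line) instance is encoded on
# the shared PPI topology by a 218-dimensional per-node vector with fixed
# block layout
#   [ expression (1) | CNV one-hot (3) | mutation indicators (13) |
#     drug-protein association (1) | GO embedding (200) ].

#' Fixed feature-block layout constants
#'
#' `mutation_types()` returns the 13 recognized mutation-type labels in their
#' fixed encoding order; `cnv_categories()` the three copy-number categories
#' (wild-type first, the neutral default). `feature_blocks()` returns the
#' index ranges of the five blocks inside the 218-dimensional node vector.
#'
#' @return character vector of labels, or a named list of integer index
#'   vectors.
#' @export
mutation_types <- function() {
  c("complex compound substitution", "complex in-frame deletion",
    "complex frameshift", "complex in-frame insertion",
    "frameshift deletion", "in-frame deletion",
    "frameshift insertion", "in-frame insertion",
    "nonstop extension", "silent coding substitution",
    "missense substitution", "nonsense substitution", "unknown")
}

#' @rdname mutation_types
#' @export
cnv_categories <- function() c("wild-type", "amplification", "deletion")

#' @rdname mutation_types
#' @export
feature_blocks <- function() {
  list(expression = 1L, cnv = 2:4, mutation = 5:17, association = 18L,
       go = 19:218)
}

FEATURE_DIM <- 218L
GO_DIM <- 200L

#' Construct a cell-line molecular profile
#'
#' Holds trinary differential expression (-1 down, 0 normal, +1 up), a
#' copy-number category per gene, and a set of mutation types per gene.
#' Genes absent from a map take the neutral category (0 expression,
#' wild-type CNV, no mutations).
#'
#' @param cell_line_id identifier string.
#' @param expression named numeric vector of -1/0/+1 values (gene -> value).
#' @param cnv named character vector of categories from [cnv_categories()].
#' @param mutations named list: gene -> character vector of types from
#'   [mutation_types()].
#' @return an object of class `cell_line_profile`.
#' @export
cell_line_profile <- function(cell_line_id, expression = numeric(0),
                              cnv = character(0), mutations = list()) {
  if (length(expression) && !all(expression %in% c(-1, 0, 1))) {
    stop("expression values must be in {-1, 0, +1}")
  }
  if (length(cnv) && !all(cnv %in% cnv_categories())) {
    stop("unknown CNV category: ",
         paste(setdiff(cnv, cnv_categories()), collapse = ", "))
  }
  if (length(mutations)) {
    bad <- setdiff(unique(unlist(mutations)), mutation_types())
    if (length(bad)) stop("unknown mutation type: ", paste(bad, collapse = ", "))
  }
  structure(list(cell_line_id = cell_line_id, expression = expression,
                 cnv = cnv, mutations = mutations),
            class = "cell_line_profile")
}

#' Construct a drug record
#'
#' @param drug_id identifier string.
#' @param associations named numeric vector protein -> association confidence
#'   score; scores live on the STITCH-style scale \[150, 999\].
#' @param smiles optional SMILES string (used only by fingerprint backends).
#' @param fingerprint optional precomputed [fingerprint()].
#' @return an object of class `drug_record`.
#' @export
drug_record <- function(drug_id, associations = numeric(0), smiles = NULL,
                        fingerprint = NULL) {
  if (length(associations)) {
    if (is.null(names(associations))) stop("associations must be named by protein")
    if (any(associations < 150 | associations > 999)) {
      stop("association scores must lie in [150, 999] for drug ", drug_id)
    }
  }
  structure(list(drug_id = drug_id, associations = associations,
                 smiles = smiles, fingerprint = fingerprint),
            class = "drug_record")
}

#' One-hot encode a copy-number category
#'
#' Fixed order (wild-type, amplification, deletion); `NA` or missing genes
#' default to wild-type.
#'
#' @param category a category string from [cnv_categories()] (or `NA`).
#' @return a length-3 0/1 vector summing to 1.
#' @export
encode_cnv <- function(category) {
  if (is.na(category) || is.null(category)) category <- "wild-type"
  i <- match(category, cnv_categories())
  if (is.na(i)) stop("unknown CNV category: ", category)
  v <- numeric(3)
  v[i] <- 1
  v
}

#' Binary-encode a set of mutation types
#'
#' One indicator per recognized type, in the fixed [mutation_types()] order;
#' a gene may carry several types.
#'
#' @param types character vector (possibly empty) of mutation types.
#' @return a length-13 0/1 vector.
#' @export
encode_mutations <- function(types) {
  v <- numeric(13)
  if (length(types) == 0) return(v)
  i <- match(types, mutation_types())
  if (anyNA(i)) stop("unknown mutation type: ", types[which(is.na(i))[1]])
  v[i] <- 1
  v
}

#' Load a gene -> 200-dim GO-embedding table
#'
#' TSV format `gene<TAB>v1<TAB>...<TAB>v200`. Each gene's row is the
#' precomputed sum of the embeddings of its associated GO terms.
#'
#' @param path TSV path.
#' @param header logical.
#' @return a `go_table`: numeric matrix with genes as rownames, 200 columns.
#' @export
read_go_table <- function(path, header = TRUE) {
  dt <- data.table::fread(path, header = header, sep = "\t")
  m <- as.matrix(dt[, -1])
  if (ncol(m) != GO_DIM) {
    stop("GO table must have ", GO_DIM, " embedding columns, found ", ncol(m))
  }
  dimnames(m) <- list(as.character(dt[[1]]), NULL)
  storage.mode(m) <- "double"
  class(m) <- c("go_table", class(m))
  m
}

#' Build a `go_table` from an in-memory matrix
#' @param m numeric matrix, genes as rownames, 200 columns.
#' @return a `go_table`.
#' @export
go_table <- function(m) {
  if (ncol(m) != GO_DIM) stop("GO vectors must have length ", GO_DIM)
  if (is.null(rownames(m))) stop("GO table needs gene rownames")
  storage.mode(m) <- "double"
  class(m) <- c("go_table", class(m))
  m
}

#' GO-embedding lookup for one gene
#'
#' Returns the gene's precomputed summation embedding, or a zero vector for a
#' gene absent from the table.
#'
#' @param gene gene identifier.
#' @param table a `go_table`.
#' @return numeric vector of length 200.
#' @export
embed_go <- function(gene, table) {
  i <- match(gene, rownames(table))
  if (is.na(i)) return(numeric(GO_DIM))
  as.numeric(table[i, ])
}

#' Combined drug-protein association feature
#'
#' One affinity value per node: the maximum of the two drugs' association
#' scores for the protein, min-max rescaled from the raw \[150, 999\] scale
#' to \[0, 1\] so the block is commensurate with the other feature blocks;
#' 0 when neither drug associates with the protein. Set `rescale = FALSE`
#' to keep the raw score scale.
#'
#' @param protein protein identifier.
#' @param drug_a,drug_b [drug_record()]s.
#' @param rescale logical, default TRUE.
#' @return a single real.
#' @export
node_association <- function(protein, drug_a, drug_b, rescale = TRUE) {
  s <- c(drug_a$associations[protein], drug_b$associations[protein])
  s <- s[!is.na(s)]
  if (length(s) == 0) return(0)
  if (any(s < 150 | s > 999)) stop("association score outside [150, 999]")
  s <- max(s)
  if (rescale) (s - 150) / (999 - 150) else s
}

#' Assemble the featured graph of one synergy instance
#'
#' Maps a cell line's genomic alterations, GO embeddings, and the two drugs'
#' protein-association scores onto the PPI topology, producing one
#' 218-dimensional feature vector per node in the fixed block order. Target
#' node sets (proteins with a recorded association for each drug) are
#' recorded; the two drugs may share targets.
#'
#' @param ppi a [ppi_network()].
#' @param profile a [cell_line_profile()].
#' @param drug_a,drug_b distinct [drug_record()]s.
#' @param label `"synergy"`, `"antagonism"`, or `NA`.
#' @param go a `go_table` ([read_go_table()]), or NULL for all-zero GO blocks.
#' @param rescale_association passed to [node_association()].
#' @return an object of class `featured_graph`: fields `topology`,
#'   `features` (n_nodes x 218 matrix, rownames = nodes), `target_nodes_a`,
#'   `target_nodes_b`, `instance` (list drug_a, drug_b, cell_line, label).
#' @export
build_featured_graph <- function(ppi, profile, drug_a, drug_b, label = NA,
                                 go = NULL, rescale_association = TRUE) {
  if (identical(drug_a$drug_id, drug_b$drug_id)) {
    stop("the two drugs of an instance must be distinct")
  }
  if (!inherits(profile, "cell_line_profile")) stop("missing cell-line profile")
  nodes <- ppi$nodes
  n <- length(nodes)
  X <- matrix(0, nrow = n, ncol = FEATURE_DIM, dimnames = list(nodes, NULL))
  bl <- feature_blocks()

  expr <- profile$expression[nodes]
  expr[is.na(expr)] <- 0
  X[, bl$expression] <- as.numeric(expr)

  X[, bl$cnv[1]] <- 1   # wild-type default
  cn <- profile$cnv[nodes]
  hit <- which(!is.na(cn))
  for (i in hit) {
    X[i, bl$cnv] <- encode_cnv(cn[[i]])
  }

  mut_genes <- intersect(names(profile$mutations), nodes)
  for (g in mut_genes) {
    X[g, bl$mutation] <- encode_mutations(profile$mutations[[g]])
  }

  sa <- drug_a$associations
  sb <- drug_b$associations
  assoc <- numeric(n)
  ia <- match(names(sa), nodes); ok <- !is.na(ia)
  assoc[ia[ok]] <- pmax(assoc[ia[ok]], sa[ok])
  ib <- match(names(sb), nodes); ok <- !is.na(ib)
  assoc[ib[ok]] <- pmax(assoc[ib[ok]], sb[ok])
  if (any(assoc > 0 & (assoc < 150 | assoc > 999))) {
    stop("association score outside [150, 999]")
  }
  if (rescale_association) {
    assoc[assoc > 0] <- (assoc[assoc > 0] - 150) / (999 - 150)
  }
  X[, bl$association] <- assoc

  if (!is.null(go)) {
    gi <- match(nodes, rownames(go))
    found <- which(!is.na(gi))
    if (length(found)) X[found, bl$go] <- go[gi[found], , drop = FALSE]
  }

  structure(list(
    topology = ppi,
    features = X,
    target_nodes_a = intersect(names(sa), nodes),
    target_nodes_b = intersect(names(sb), nodes),
    instance = list(drug_a = drug_a$drug_id, drug_b = drug_b$drug_id,
                    cell_line = profile$cell_line_id, label = label)
  ), class = "featured_graph")
}

#' @export
print.featured_graph <- function(x, ...) {
  cat(sprintf(
    "featured_graph: %s + %s on %s | %d nodes x %d features | label %s\n",
    x$instance$drug_a, x$instance$drug_b, x$instance$cell_line,
    nrow(x$features), ncol(x$features), as.character(x$instance$label)))
  invisible(x)
}
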