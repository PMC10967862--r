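# Synthetic-data generator: emulates the five pipeline inputs (PPI network,
# cell-line profiles, GO-embedding table, drug library, synergy table) with
# configurable sizes and a planted, learnable label rule, so every module is
# testable without external downloads.
#
# The planted rule routes the label signal through exactly the structures
# the model consumes: a pair is synergistic when its drugs' combined targets
# hit the cell line's dysregulated gene module (coverage) without being
# redundant with each other (target overlap), flipped with a small noise
# rate. The default configuration targets the ~77/23 synergy/antagonism
# class prior of real anticancer synergy collections.

#' Synthetic-data configuration
#'
#' Defaults describe the pinned desk-scale world used across the test suite:
#' a 160-protein degree-heterogeneous (preferential-attachment) network with
#' mean degree ~6 (matching the degree scale of reduced instance graphs),
#' 75% druggable nodes (druggable/non-druggable ratio ~3, the regime of
#' drug-target-annotated human PPI networks), 60 drugs in 12 similarity
#' families (so the DACS filter has realistic pass/fail structure), 8 cell
#' lines with ~15% dysregulated expression concentrated in a per-line
#' 25-gene module, and 300 drug-pair instances labeled by the planted
#' coverage rule with 5% label noise (defaults chosen to land the synergy
#' class prior in the ~77/23 regime of curated synergy collections).
#'
#' @param n_proteins number of PPI nodes.
#' @param mean_degree target average node degree.
#' @param druggable_fraction fraction of druggable nodes.
#' @param n_drugs,n_families drug library size and similarity families.
#' @param targets_per_drug integer range (min, max) of targets per drug.
#' @param fp_width,fp_bits_per_family fingerprint width and family bit count.
#' @param fp_keep_prob,fp_extra_bits per-drug family-bit retention
#'   probability and count of private random bits.
#' @param family_pool_size size of each family's shared target pool.
#' @param target_keep_prob per-drug retention probability of family target
#'   pool members. Targets are drawn from the family pool only, keeping
#'   family members pharmacologically coherent — the premise label-transfer
#'   augmentation rests on.
#' @param n_cell_lines,module_size cell lines and dysregulated-module size.
#' @param expression_sparsity genome-wide fraction of +/-1 expression calls.
#' @param cnv_rate,mutation_rate per-gene alteration probabilities.
#' @param go_dim GO-embedding dimension (fixed 200).
#' @param n_pairs number of synergy instances.
#' @param cover_min,overlap_max planted-rule parameters: minimum distinct
#'   dysregulated-module targets jointly covered, maximum target-set overlap.
#' @param noise_rate label flip probability.
#' @param seed integer RNG seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 160L, mean_degree = 6,
                         druggable_fraction = 0.75,
                         n_drugs = 60L, n_families = 12L,
                         targets_per_drug = c(4L, 8L),
                         fp_width = 256L, fp_bits_per_family = 40L,
                         fp_keep_prob = 0.9, fp_extra_bits = 6L,
                         family_pool_size = 10L, target_keep_prob = 0.75,
                         n_cell_lines = 8L, module_size = 25L,
                         expression_sparsity = 0.15,
                         cnv_rate = 0.05, mutation_rate = 0.10,
                         go_dim = 200L, n_pairs = 600L,
                         cover_min = 1L, overlap_max = 3L,
                         noise_rate = 0.05, seed = 17L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins > 0, cfg$n_drugs > 1, cfg$n_cell_lines > 0,
            cfg$noise_rate >= 0, cfg$noise_rate <= 1,
            cfg$expression_sparsity >= 0, cfg$expression_sparsity <= 1,
            cfg$go_dim == 200L)
  class(cfg) <- "synth_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate a synthetic PPI network
#'
#' Preferential-attachment random graph (degree-heterogeneous, connected by
#' construction) with `mean_degree`/2 edges added per arriving node, node ids
#' `P0001...`, and druggable flags drawn at the configured fraction.
#'
#' @param cfg a [synth_config()].
#' @return a [ppi_network()].
#' @export
make_ppi <- function(cfg) {
  m <- max(1L, round(cfg$mean_degree / 2))
  if (m >= cfg$n_proteins) stop("mean degree infeasible for n_proteins")
  with_seed(cfg$seed, {
    ig <- igraph::sample_pa(cfg$n_proteins, m = m, directed = FALSE)
    nodes <- sprintf("P%04d", seq_len(cfg$n_proteins))
    ed <- igraph::as_edgelist(ig, names = FALSE)
    drug <- runif(cfg$n_proteins) < cfg$druggable_fraction
    ppi_network(nodes,
                cbind(nodes[ed[, 1]], nodes[ed[, 2]]),
                druggable = drug)
  })
}

#' Generate a synthetic drug library
#'
#' Drugs are grouped into similarity families. Each family owns a base
#' fingerprint bit set and a shared target pool drawn from the druggable
#' nodes; a member drug keeps each family fingerprint bit with the
#' configured probability (plus a few private random bits) and draws its
#' target set from the family pool only, so within-family pairs show high
#' Tanimoto and target-profile MCC (passing the DACS filter) while
#' between-family pairs do not, and family members remain
#' pharmacologically coherent. Association scores are uniform on
#' \[150, 999\].
#'
#' @param cfg a [synth_config()].
#' @param ppi the [make_ppi()] network.
#' @return a [drug_library()].
#' @export
make_drugs <- function(cfg, ppi) {
  druggable_nodes <- ppi$nodes[ppi$druggable]
  with_seed(cfg$seed + 1L, {
    fam_bits <- lapply(seq_len(cfg$n_families), function(i)
      sample.int(cfg$fp_width, cfg$fp_bits_per_family))
    pool_size <- max(cfg$family_pool_size, max(cfg$targets_per_drug))
    fam_targets <- lapply(seq_len(cfg$n_families), function(i)
      sample(druggable_nodes, pool_size))
    drugs <- lapply(seq_len(cfg$n_drugs), function(i) {
      fam <- ((i - 1L) %% cfg$n_families) + 1L
      bits <- fam_bits[[fam]][runif(cfg$fp_bits_per_family) < cfg$fp_keep_prob]
      bits <- union(bits, sample.int(cfg$fp_width, cfg$fp_extra_bits))
      pool <- fam_targets[[fam]]
      kept <- pool[runif(pool_size) < cfg$target_keep_prob]
      lo <- cfg$targets_per_drug[1]; hi <- cfg$targets_per_drug[2]
      if (length(kept) < lo) {
        kept <- union(kept, sample(setdiff(pool, kept), lo - length(kept)))
      } else if (length(kept) > hi) {
        kept <- kept[seq_len(hi)]
      }
      scores <- stats::setNames(round(runif(length(kept), 150, 999)), kept)
      drug_record(sprintf("D%03d", i), associations = scores,
                  fingerprint = fingerprint(bits, cfg$fp_width))
    })
    drug_library(drugs, ppi, fp_width = cfg$fp_width)
  })
}

#' Generate synthetic cell-line profiles
#'
#' Each cell line carries a dysregulated gene module (used by the planted
#' label rule): module genes are dysregulated (+1/-1) with probability 0.9,
#' background genes at the rate that brings the genome-wide dysregulation
#' fraction to `expression_sparsity`. CNV and mutation assignments are drawn
#' independently at their configured rates.
#'
#' @param cfg a [synth_config()].
#' @param ppi the network (supplies the gene universe).
#' @return list with `profiles` (list of [cell_line_profile()]s) and
#'   `modules` (named list cell line -> module gene set).
#' @export
make_cell_lines <- function(cfg, ppi) {
  genes <- ppi$nodes
  n <- length(genes)
  msize <- min(cfg$module_size, n)
  with_seed(cfg$seed + 2L, {
    modules <- list()
    profiles <- list()
    for (i in seq_len(cfg$n_cell_lines)) {
      id <- sprintf("CL%02d", i)
      module <- sample(genes, msize)
      p_bg <- max(0, (cfg$expression_sparsity * n - 0.9 * msize) / (n - msize))
      dys <- ifelse(genes %in% module, 0.9, p_bg)
      hit <- runif(n) < dys
      expr <- stats::setNames(numeric(n), genes)
      expr[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE)
      cn_draw <- runif(n)
      cnv <- character(0)
      amp <- genes[cn_draw < cfg$cnv_rate / 2]
      del <- genes[cn_draw >= cfg$cnv_rate / 2 & cn_draw < cfg$cnv_rate]
      cnv <- stats::setNames(c(rep("amplification", length(amp)),
                               rep("deletion", length(del))), c(amp, del))
      mut_genes <- genes[runif(n) < cfg$mutation_rate]
      mutations <- lapply(mut_genes, function(g)
        sample(mutation_types(), sample(1:2, 1)))
      names(mutations) <- mut_genes
      profiles[[id]] <- cell_line_profile(id, expression = expr[expr != 0],
                                          cnv = cnv, mutations = mutations)
      modules[[id]] <- module
    }
    list(profiles = profiles, modules = modules)
  })
}

#' Generate a synthetic GO-embedding table
#'
#' Independent Gaussian 200-dimensional embeddings per gene (scale 0.3),
#' standing in for summed ontology-term embeddings.
#'
#' @param cfg a [synth_config()].
#' @param ppi the network.
#' @return a `go_table`.
#' @export
make_go_table <- function(cfg, ppi) {
  with_seed(cfg$seed + 3L, {
    m <- matrix(rnorm(length(ppi$nodes) * cfg$go_dim, sd = 0.3),
                nrow = length(ppi$nodes),
                dimnames = list(ppi$nodes, NULL))
    go_table(m)
  })
}

#' Generate labeled synergy instances with the planted rule
#'
#' Samples `n_pairs` distinct (unordered drug pair, cell line) combinations
#' and labels each `"synergy"` iff the union of the two drugs' target sets
#' covers at least `cover_min` of the cell line's dysregulated genes
#' (realized expression != 0, which concentrates in the line's module)
#' while the target-set overlap is at most `overlap_max` (redundant pairs
#' hitting the same proteins are antagonistic); labels flip with
#' probability `noise_rate`. Because the rule is stated on realized
#' expression, the signal is carried exactly by the features the model
#' consumes: target nodes (nonzero association) with nonzero expression.
#'
#' @param cfg a [synth_config()].
#' @param library a [drug_library()].
#' @param cell_lines a [make_cell_lines()] result.
#' @return a synergy `data.table` (provenance `"original"`).
#' @export
make_labels <- function(cfg, library, cell_lines) {
  ids <- names(library$drugs)
  cls <- names(cell_lines$profiles)
  with_seed(cfg$seed + 4L, {
    combos <- expand.grid(a = seq_along(ids), b = seq_along(ids),
                          cl = seq_along(cls))
    combos <- combos[combos$a < combos$b, ]
    take <- combos[sample.int(nrow(combos), min(cfg$n_pairs, nrow(combos))), ]
    dysreg <- lapply(cell_lines$profiles, function(p)
      names(p$expression)[p$expression != 0])
    lab <- character(nrow(take))
    for (i in seq_len(nrow(take))) {
      ta <- names(library$drugs[[take$a[i]]]$associations)
      tb <- names(library$drugs[[take$b[i]]]$associations)
      cover <- length(intersect(union(ta, tb), dysreg[[cls[take$cl[i]]]]))
      overlap <- length(intersect(ta, tb))
      synergy <- (cover >= cfg$cover_min) && (overlap <= cfg$overlap_max)
      if (runif(1) < cfg$noise_rate) synergy <- !synergy
      lab[i] <- if (synergy) "synergy" else "antagonism"
    }
    synergy_table(ids[take$a], ids[take$b], cls[take$cl], lab)
  })
}

#' Generate the full synthetic bundle
#'
#' Builds the network, drug library, cell-line profiles, GO table, and
#' labeled synergy instances; with `dir` set, also writes every
#' external-interface file (edge list, node table, per-cell-line profile
#' TSVs, GO table, drug target/fingerprint tables, synergy TSV) plus a
#' `manifest.json` recording the configuration, seed and file checksums.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory.
#' @return a list of class `synth_bundle`: `ppi`, `library`, `profiles`,
#'   `modules`, `go`, `synergy`, `cfg`.
#' @export
make_dataset <- function(cfg = synth_config(), dir = NULL) {
  ppi <- make_ppi(cfg)
  library <- make_drugs(cfg, ppi)
  cl <- make_cell_lines(cfg, ppi)
  go <- make_go_table(cfg, ppi)
  synergy <- make_labels(cfg, library, cl)
  bundle <- structure(list(ppi = ppi, library = library,
                           profiles = cl$profiles, modules = cl$modules,
                           go = go, synergy = synergy, cfg = cfg),
                      class = "synth_bundle")
  if (!is.null(dir)) write_dataset(bundle, dir)
  bundle
}

#' @rdname make_dataset
#' @param bundle a `synth_bundle`.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_ppi_network(bundle$ppi, fp("edges.tsv"), fp("nodes.tsv"))
  go_dt <- data.table::data.table(gene = rownames(bundle$go))
  go_dt <- cbind(go_dt, data.table::as.data.table(unclass(bundle$go)))
  data.table::fwrite(go_dt, fp("go.tsv"), sep = "\t")
  assoc <- data.table::rbindlist(lapply(bundle$library$drugs, function(d)
    data.table::data.table(drug_id = d$drug_id,
                           protein = names(d$associations),
                           score = unname(d$associations))))
  data.table::fwrite(assoc, fp("drug_targets.tsv"), sep = "\t")
  fps <- data.table::rbindlist(lapply(bundle$library$drugs, function(d) {
    f <- bundle$library$fingerprints[[d$drug_id]]
    data.table::data.table(drug_id = d$drug_id,
                           bits = paste(f$bits, collapse = ","),
                           width = f$width)
  }))
  data.table::fwrite(fps, fp("drug_fingerprints.tsv"), sep = "\t")
  for (id in names(bundle$profiles)) {
    p <- bundle$profiles[[id]]
    data.table::fwrite(data.table::data.table(
      gene = names(p$expression), expression = unname(p$expression)),
      fp(paste0(id, "_expression.tsv")), sep = "\t")
    data.table::fwrite(data.table::data.table(
      gene = names(p$cnv), cnv_category = unname(p$cnv)),
      fp(paste0(id, "_cnv.tsv")), sep = "\t")
    mut <- data.table::rbindlist(lapply(names(p$mutations), function(g)
      data.table::data.table(gene = g, mutation_type = p$mutations[[g]])))
    if (nrow(mut) == 0) mut <- data.table::data.table(gene = character(0),
                                                      mutation_type = character(0))
    data.table::fwrite(mut, fp(paste0(id, "_mutations.tsv")), sep = "\t")
  }
  write_synergy_table(bundle$synergy, fp("synergy.tsv"))
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  checks <- as.list(tools::md5sum(file.path(dir, files)))
  names(checks) <- files
  jsonlite::write_json(
    list(config = unclass(bundle$cfg), seed = bundle$cfg$seed,
         checksums = checks),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

#' Read a synthetic bundle back from disk
#' @param dir directory written by [write_dataset()].
#' @return a `synth_bundle` (without `modules`, which are generator-internal).
#' @export
read_dataset <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  manifest <- jsonlite::read_json(fp("manifest.json"), simplifyVector = TRUE)
  cfg <- do.call(synth_config, as.list(manifest$config)[names(formals(synth_config))])
  ppi <- read_ppi_network(fp("edges.tsv"), fp("nodes.tsv"), min_confidence = 0)
  go <- read_go_table(fp("go.tsv"))
  assoc <- data.table::fread(fp("drug_targets.tsv"), sep = "\t")
  fps <- data.table::fread(fp("drug_fingerprints.tsv"), sep = "\t")
  drugs <- lapply(fps$drug_id, function(id) {
    rows <- assoc[assoc$drug_id == id]
    bits <- as.integer(strsplit(fps$bits[fps$drug_id == id], ",")[[1]])
    drug_record(id,
                associations = stats::setNames(rows$score, rows$protein),
                fingerprint = fingerprint(bits,
                                          fps$width[fps$drug_id == id]))
  })
  library <- drug_library(drugs, ppi)
  prof_files <- list.files(dir, pattern = "_expression\\.tsv$")
  ids <- sub("_expression\\.tsv$", "", prof_files)
  profiles <- lapply(ids, function(id) {
    ex <- data.table::fread(fp(paste0(id, "_expression.tsv")), sep = "\t")
    cn <- data.table::fread(fp(paste0(id, "_cnv.tsv")), sep = "\t")
    mu <- data.table::fread(fp(paste0(id, "_mutations.tsv")), sep = "\t")
    muts <- if (nrow(mu)) split(mu$mutation_type, mu$gene) else list()
    cell_line_profile(id,
                      expression = stats::setNames(ex$expression, ex$gene),
                      cnv = if (nrow(cn)) stats::setNames(cn$cnv_category, cn$gene)
                            else character(0),
                      mutations = muts)
  })
  names(profiles) <- ids
  structure(list(ppi = ppi, library = library, profiles = profiles,
                 modules = NULL, go = go,
                 synergy = read_synergy_table(fp("synergy.tsv")), cfg = cfg),
            class = "synth_bundle")
}

#' Build reduced graphs for a set of synergy instances
#'
#' Convenience driver: for each instance row, assembles the featured graph
#' and reduces it. Since instances on the same (pair, cell line) share their
#' graph, results are keyed and cached by instance id.
#'
#' @param bundle a `synth_bundle` (or any list with `ppi`, `library`,
#'   `profiles`, `go`).
#' @param instances a synergy table.
#' @param verbose print progress every 100 graphs.
#' @return named list instance id -> `reduced_graph`.
#' @export
build_instance_graphs <- function(bundle, instances, verbose = FALSE) {
  out <- vector("list", nrow(instances))
  names(out) <- instances$id
  for (i in seq_len(nrow(instances))) {
    id <- instances$id[i]
    if (!is.null(out[[id]]) && i > 1) next
    fg <- build_featured_graph(
      bundle$ppi, bundle$profiles[[instances$cell_line[i]]],
      bundle$library$drugs[[instances$drug_a[i]]],
      bundle$library$drugs[[instances$drug_b[i]]],
      label = instances$label[i], go = bundle$go)
    out[[id]] <- reduce_graph(fg)
    if (verbose && i %% 100 == 0) message("reduced ", i, "/", nrow(instances))
  }
  out
}
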