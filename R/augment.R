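# DACS-based data augmentation: new labeled instances are created by
# substituting one drug of an original pair with library drugs that pass a
# combined structural (Tanimoto) and target-profile (MCC) similarity filter,
# transferring the parent label.

#' Construct a molecular fingerprint
#'
#' A fingerprint is a fixed-width bit set; similarity is measured by the
#' Tanimoto coefficient over set bits. Fingerprints can be supplied directly
#' (e.g. by the synthetic generator) or derived from a SMILES string with
#' [fingerprint_from_smiles()], a deterministic path-based hashing scheme
#' (linear substrings of length 1-7 hashed into the bit space) standing in
#' for toolkit-specific path fingerprints.
#'
#' @param bits integer vector of set bit positions (1-based).
#' @param width total bit width (default 1024).
#' @return an object of class `fingerprint`.
#' @export
fingerprint <- function(bits, width = 1024L) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > width)) {
    stop("bit positions must lie in [1, width]")
  }
  structure(list(bits = bits, width = as.integer(width)), class = "fingerprint")
}

#' @rdname fingerprint
#' @param smiles a SMILES string.
#' @param max_len maximum substring (path proxy) length.
#' @export
fingerprint_from_smiles <- function(smiles, width = 1024L, max_len = 7L) {
  if (is.null(smiles) || is.na(smiles) || !nzchar(smiles)) {
    stop("fingerprint requires a non-empty SMILES string")
  }
  ch <- utf8ToInt(smiles)
  n <- length(ch)
  bits <- integer(0)
  for (len in seq_len(min(max_len, n))) {
    for (s in seq_len(n - len + 1L)) {
      h <- 0
      for (k in seq_len(len)) h <- (h * 131 + ch[s + k - 1L]) %% 1048573
      bits <- c(bits, (h %% width) + 1L)
    }
  }
  fingerprint(bits, width)
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits; defined as 0 when both
#' fingerprints are empty.
#'
#' @param f1,f2 [fingerprint()]s of equal width.
#' @return a real in \[0, 1\].
#' @export
tanimoto <- function(f1, f2) {
  if (f1$width != f2$width) stop("fingerprint width mismatch")
  i <- length(intersect(f1$bits, f2$bits))
  u <- length(f1$bits) + length(f2$bits) - i
  if (u == 0) return(0)
  i / u
}

#' Binary target profile of a drug over the PPI node set
#'
#' @param drug a [drug_record()].
#' @param ppi a [ppi_network()] (supplies the node universe).
#' @return a logical vector named by node, TRUE where the drug has a
#'   recorded association.
#' @export
target_profile <- function(drug, ppi) {
  p <- stats::setNames(rep(FALSE, length(ppi$nodes)), ppi$nodes)
  hit <- intersect(names(drug$associations), ppi$nodes)
  p[hit] <- TRUE
  p
}

mcc_from_counts <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Matthews correlation coefficient of two binary target profiles
#'
#' MCC of the 2x2 contingency table of the paired vectors; 0 when either
#' vector is constant (degenerate contingency).
#'
#' @param p1,p2 logical (or 0/1) vectors of equal length.
#' @return a real in \[-1, 1\].
#' @export
target_mcc <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("target profile length mismatch")
  p1 <- as.logical(p1); p2 <- as.logical(p2)
  mcc_from_counts(tp = sum(p1 & p2), fp = sum(!p1 & p2),
                  fn = sum(p1 & !p2), tn = sum(!p1 & !p2))
}

#' Build a drug library with precomputed fingerprints and target profiles
#'
#' @param drugs list of [drug_record()]s (each with a fingerprint or SMILES).
#' @param ppi the shared [ppi_network()].
#' @param fp_width fingerprint width for SMILES-derived fingerprints.
#' @return an object of class `drug_library`: `drugs` (named list),
#'   `fingerprints` (named list), `profiles` (drugs x nodes logical matrix).
#' @export
drug_library <- function(drugs, ppi, fp_width = 1024L) {
  ids <- vapply(drugs, `[[`, "", "drug_id")
  if (anyDuplicated(ids)) stop("duplicate drug ids in library")
  names(drugs) <- ids
  fps <- lapply(drugs, function(d) {
    if (!is.null(d$fingerprint)) return(d$fingerprint)
    if (is.null(d$smiles)) stop("drug ", d$drug_id,
                                " has neither fingerprint nor SMILES")
    fingerprint_from_smiles(d$smiles, width = fp_width)
  })
  prof <- t(vapply(drugs, function(d) target_profile(d, ppi),
                   logical(length(ppi$nodes))))
  rownames(prof) <- ids
  structure(list(drugs = drugs, fingerprints = fps, profiles = prof,
                 ppi_nodes = ppi$nodes),
            class = "drug_library")
}

#' Read a drug library from TSV tables
#'
#' `targets_path` is a STITCH-style association table
#' `drug_id<TAB>protein<TAB>score` (scores in \[150, 999\]); fingerprints
#' come either from `smiles_path` (`drug_id<TAB>smiles`, hashed via
#' [fingerprint_from_smiles()]) or from `fingerprints_path`
#' (`drug_id<TAB>bits<TAB>width`, bits comma-separated).
#'
#' @param targets_path association TSV.
#' @param ppi the shared [ppi_network()].
#' @param smiles_path,fingerprints_path one of the two fingerprint sources.
#' @param fp_width width for SMILES-derived fingerprints.
#' @return a [drug_library()].
#' @export
read_drug_library <- function(targets_path, ppi, smiles_path = NULL,
                              fingerprints_path = NULL, fp_width = 1024L) {
  assoc <- data.table::fread(targets_path, sep = "\t")
  smiles <- if (!is.null(smiles_path)) {
    s <- data.table::fread(smiles_path, sep = "\t")
    stats::setNames(as.character(s[[2]]), as.character(s[[1]]))
  }
  fps <- if (!is.null(fingerprints_path)) {
    f <- data.table::fread(fingerprints_path, sep = "\t")
    stats::setNames(lapply(seq_len(nrow(f)), function(i)
      fingerprint(as.integer(strsplit(as.character(f$bits[i]), ",")[[1]]),
                  f$width[i])),
      as.character(f$drug_id))
  }
  ids <- unique(as.character(assoc[[1]]))
  drugs <- lapply(ids, function(id) {
    rows <- assoc[as.character(assoc[[1]]) == id]
    drug_record(id,
                associations = stats::setNames(as.numeric(rows[[3]]),
                                               as.character(rows[[2]])),
                smiles = if (!is.null(smiles)) unname(smiles[id]),
                fingerprint = if (!is.null(fps)) fps[[id]])
  })
  drug_library(drugs, ppi, fp_width = fp_width)
}

#' Drug action/chemical similarity (DACS) of two library drugs
#'
#' Combines structural similarity (Tanimoto coefficient TC of the two
#' fingerprints) and molecular-target similarity (MCC of the binary target
#' profiles over the PPI node set) into
#' `dacs = w * TC + (1 - w) * (MCC + 1) / 2` with default `w = 0.5` (the MCC
#' term is mapped from \[-1, 1\] to \[0, 1\] so both terms share a scale).
#' Pass flags follow the standard thresholds: structural diversity requires
#' `TC <= tc_max` (default 0.95; TC above 0.95 is effective identity) and
#' pharmacological similarity requires `dacs >= dacs_min` (default 0.53).
#'
#' @param a,b drug ids resolved in `library`.
#' @param library a [drug_library()].
#' @param w weight of the Tanimoto term in \[0, 1\].
#' @param tc_max,dacs_min pass thresholds.
#' @return an object of class `dacs_result`: `tc`, `target_mcc`, `dacs`,
#'   `passes_tc`, `passes_dacs`, plus the thresholds used.
#' @export
dacs_score <- function(a, b, library, w = 0.5, tc_max = 0.95,
                       dacs_min = 0.53) {
  for (id in c(a, b)) {
    if (!id %in% names(library$drugs)) stop("drug not in library: ", id)
  }
  tc <- tanimoto(library$fingerprints[[a]], library$fingerprints[[b]])
  mcc <- target_mcc(library$profiles[a, ], library$profiles[b, ])
  dacs <- w * tc + (1 - w) * (mcc + 1) / 2
  structure(list(tc = tc, target_mcc = mcc, dacs = dacs,
                 passes_tc = tc <= tc_max, passes_dacs = dacs >= dacs_min,
                 tc_max = tc_max, dacs_min = dacs_min),
            class = "dacs_result")
}

#' Candidate substitute drugs for augmentation
#'
#' Scores every library drug (excluding the query) against the query drug
#' with [dacs_score()] and returns those passing both the Tanimoto-diversity
#' and the DACS-similarity filters, sorted by DACS descending with ties
#' broken by drug id.
#'
#' @param drug_id query drug id.
#' @param library a [drug_library()].
#' @inheritParams dacs_score
#' @return a data.frame with columns `drug_id`, `tc`, `target_mcc`, `dacs`.
#' @export
candidate_substitutes <- function(drug_id, library, tc_max = 0.95,
                                  dacs_min = 0.53, w = 0.5) {
  others <- setdiff(names(library$drugs), drug_id)
  if (length(others) == 0) {
    return(data.frame(drug_id = character(0), tc = numeric(0),
                      target_mcc = numeric(0), dacs = numeric(0)))
  }
  res <- lapply(others, function(o) dacs_score(drug_id, o, library, w = w,
                                               tc_max = tc_max,
                                               dacs_min = dacs_min))
  df <- data.frame(
    drug_id = others,
    tc = vapply(res, `[[`, 0, "tc"),
    target_mcc = vapply(res, `[[`, 0, "target_mcc"),
    dacs = vapply(res, `[[`, 0, "dacs"),
    stringsAsFactors = FALSE)
  df <- df[vapply(res, `[[`, TRUE, "passes_tc") &
             vapply(res, `[[`, TRUE, "passes_dacs"), , drop = FALSE]
  df <- df[order(-df$dacs, df$drug_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a synergy-instance table
#'
#' The canonical tabular form of synergy data: one row per instance with
#' columns `drug_a`, `drug_b`, `cell_line`, `label` (`"synergy"` /
#' `"antagonism"`), `provenance` (`"original"` or `"augmented"`), `parent`
#' (parent instance id for augmented rows, `NA` otherwise) and `slot`
#' (which drug was substituted, `"a"`/`"b"`/`NA`). Instance ids are
#' `drug_a|drug_b|cell_line`.
#'
#' @param drug_a,drug_b,cell_line,label character vectors (recycled).
#' @param provenance,parent,slot optional character vectors.
#' @return a `data.table` with an `id` column.
#' @export
synergy_table <- function(drug_a, drug_b, cell_line, label,
                          provenance = "original", parent = NA_character_,
                          slot = NA_character_) {
  if (any(drug_a == drug_b)) stop("degenerate pair: drug_a == drug_b")
  if (!all(label %in% c("synergy", "antagonism"))) {
    stop("labels must be 'synergy' or 'antagonism'")
  }
  dt <- data.table::data.table(
    drug_a = drug_a, drug_b = drug_b, cell_line = cell_line, label = label,
    provenance = provenance, parent = parent, slot = slot)
  dt[, "id" := paste(drug_a, drug_b, cell_line, sep = "|")]
  dt
}

pair_key <- function(a, b, cell) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, cell, sep = "|")
}

#' Augment one synergy instance by drug substitution
#'
#' For each slot of the pair (drug B first, then drug A), every library drug
#' passing the DACS filter against the slot's drug replaces it, producing a
#' new instance on the same cell line with the parent's label transferred
#' verbatim and provenance recording the parent id and replaced slot.
#' Degenerate pairs (X:X) and pairs colliding with an existing original
#' combination on the same cell line are dropped.
#'
#' @param inst a single-row synergy table (or list with `drug_a`, `drug_b`,
#'   `cell_line`, `label`).
#' @param library a [drug_library()].
#' @param originals optional synergy table of original instances used for
#'   collision suppression.
#' @inheritParams dacs_score
#' @return a synergy `data.table` of augmented instances (possibly empty).
#' @export
augment_pair <- function(inst, library, originals = NULL, tc_max = 0.95,
                         dacs_min = 0.53, w = 0.5) {
  parent_id <- paste(inst$drug_a, inst$drug_b, inst$cell_line, sep = "|")
  out <- list()
  for (s in c("b", "a")) {
    fixed <- if (s == "b") inst$drug_a else inst$drug_b
    repl <- if (s == "b") inst$drug_b else inst$drug_a
    cand <- candidate_substitutes(repl, library, tc_max = tc_max,
                                  dacs_min = dacs_min, w = w)
    cand <- cand$drug_id[cand$drug_id != fixed]
    if (length(cand) == 0) next
    da <- if (s == "b") rep(fixed, length(cand)) else cand
    db <- if (s == "b") cand else rep(fixed, length(cand))
    out[[s]] <- synergy_table(da, db, inst$cell_line, inst$label,
                              provenance = "augmented", parent = parent_id,
                              slot = s)
  }
  if (length(out) == 0) {
    return(synergy_table(character(0), character(0), character(0),
                         character(0)))
  }
  aug <- data.table::rbindlist(out)
  if (!is.null(originals) && nrow(originals) > 0 && nrow(aug) > 0) {
    taken <- pair_key(originals$drug_a, originals$drug_b, originals$cell_line)
    aug <- aug[!pair_key(aug$drug_a, aug$drug_b, aug$cell_line) %in% taken]
  }
  aug
}

#' Augment a full synergy dataset
#'
#' Applies [augment_pair()] to every original instance; duplicate augmented
#' pairs (same unordered pair + cell line) are kept once, the first parent
#' encountered winning.
#'
#' @param originals a synergy table (provenance `"original"`).
#' @param library a [drug_library()].
#' @inheritParams dacs_score
#' @return a synergy `data.table` of augmented instances.
#' @export
augment_dataset <- function(originals, library, tc_max = 0.95,
                            dacs_min = 0.53, w = 0.5) {
  parts <- lapply(seq_len(nrow(originals)), function(i) {
    augment_pair(as.list(originals[i]), library, originals = originals,
                 tc_max = tc_max, dacs_min = dacs_min, w = w)
  })
  aug <- data.table::rbindlist(parts)
  if (nrow(aug) == 0) return(aug)
  aug[!duplicated(pair_key(aug$drug_a, aug$drug_b, aug$cell_line))]
}

#' Read / write synergy tables as TSV
#'
#' Columns `drug_a drug_b cell_line label provenance parent slot`.
#'
#' @param path TSV path.
#' @return a synergy `data.table` (read) or invisibly the table (write).
#' @export
read_synergy_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA")
  synergy_table(dt$drug_a, dt$drug_b, dt$cell_line, dt$label,
                provenance = if ("provenance" %in% names(dt)) dt$provenance
                             else "original",
                parent = if ("parent" %in% names(dt)) dt$parent
                         else NA_character_,
                slot = if ("slot" %in% names(dt)) dt$slot else NA_character_)
}

#' @rdname read_synergy_table
#' @param tab a synergy table.
#' @export
write_synergy_table <- function(tab, path) {
  data.table::fwrite(tab[, c("drug_a", "drug_b", "cell_line", "label",
                             "provenance", "parent", "slot"), with = FALSE],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(tab)
}
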