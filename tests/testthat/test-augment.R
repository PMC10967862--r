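test_that("tanimoto is the bit-set Jaccard and is symmetric", {
  f1 <- fingerprint(c(1, 2, 3), 16)
  f2 <- fingerprint(c(2, 3, 4), 16)
  expect_equal(tanimoto(f1, f2), 0.5)  # 2 shared / 4 union
  expect_equal(tanimoto(f1, f1), 1)
  expect_equal(tanimoto(f1, fingerprint(c(10, 11), 16)), 0)
  expect_equal(tanimoto(fingerprint(integer(0), 16),
                        fingerprint(integer(0), 16)), 0)
  expect_equal(tanimoto(f1, f2), tanimoto(f2, f1))
  expect_error(tanimoto(f1, fingerprint(1, 32)), "width")
  expect_error(fingerprint(99, 16), "width")
})

test_that("SMILES-derived fingerprints are deterministic", {
  fa <- fingerprint_from_smiles("CCO")
  fb <- fingerprint_from_smiles("CCO")
  expect_identical(fa, fb)
  expect_error(fingerprint_from_smiles(""), "SMILES")
})

test_that("target_mcc matches the contingency oracle and conventions", {
  p1 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  p2 <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  # contingency TP=3, FN=1, FP=1, TN=5
  expected <- (3 * 5 - 1 * 1) / sqrt((3 + 1) * (3 + 1) * (5 + 1) * (5 + 1))
  expect_equal(target_mcc(p1, p2), expected)
  expect_equal(target_mcc(p1, p2), target_mcc(p2, p1))
  expect_equal(target_mcc(p1, p1), 1)
  expect_equal(target_mcc(p1, !p1), -1)
  expect_equal(target_mcc(p1, rep(TRUE, 10)), 0)  # constant vector -> 0
  expect_error(target_mcc(p1, p2[1:5]), "length")
})

make_test_library <- function() {
  ppi <- ppi_network(sprintf("p%02d", 1:20), NULL,
                     druggable = rep(TRUE, 20))
  mk <- function(id, bits, targets) {
    drug_record(id,
                associations = stats::setNames(rep(500, length(targets)),
                                               targets),
                fingerprint = fingerprint(bits, 64))
  }
  drugs <- list(
    mk("A", 1:20, c("p01", "p02")),
    mk("B", 10:30, c("p03", "p04", "p05")),
    mk("C", 10:32, c("p03", "p04", "p06")),      # similar to B (TC ~0.91)
    mk("D", 40:60, c("p10", "p11", "p12")),      # dissimilar to B
    mk("E", c(10:29, 33), c("p03", "p05", "p07"))  # similar to B
  )
  drug_library(drugs, ppi)
}

test_that("dacs_score combines TC and rescaled MCC with threshold flags", {
  lib <- make_test_library()
  r <- dacs_score("B", "C", lib)
  expect_equal(r$tc, tanimoto(lib$fingerprints$B, lib$fingerprints$C))
  expect_equal(r$target_mcc,
               target_mcc(lib$profiles["B", ], lib$profiles["C", ]))
  expect_equal(r$dacs, 0.5 * r$tc + 0.5 * (r$target_mcc + 1) / 2)
  # identical drugs: tc = 1 violates the <= 0.95 diversity rule
  lib2 <- drug_library(list(
    drug_record("X", associations = c(p01 = 500),
                fingerprint = fingerprint(1:5, 64)),
    drug_record("Y", associations = c(p01 = 500),
                fingerprint = fingerprint(1:5, 64))),
    ppi_network(sprintf("p%02d", 1:20), NULL, druggable = rep(TRUE, 20)))
  ri <- dacs_score("X", "Y", lib2)
  expect_equal(ri$tc, 1)
  expect_equal(ri$dacs, 1)
  expect_false(ri$passes_tc)
  expect_true(ri$passes_dacs)
  expect_error(dacs_score("B", "nope", lib), "not in library")
})

test_that("dacs arithmetic under the stated default weight", {
  # tc = 0.5, mcc = 0 -> dacs = 0.5, fails at 0.53
  expect_equal(0.5 * 0.5 + 0.5 * (0 + 1) / 2, 0.5)
  # tc = 0.9, mcc = 0.6 -> dacs = 0.85, passes both
  expect_equal(0.5 * 0.9 + 0.5 * (0.6 + 1) / 2, 0.85)
})

test_that("candidate_substitutes filters, sorts, excludes the query", {
  lib <- make_test_library()
  cand <- candidate_substitutes("B", lib, tc_max = 0.95, dacs_min = 0.53)
  expect_setequal(cand$drug_id, c("C", "E"))   # D fails, A dissimilar
  expect_true(all(diff(cand$dacs) <= 0))
  # filter disabled returns full library minus query
  all_cand <- candidate_substitutes("B", lib, tc_max = 1, dacs_min = -Inf)
  expect_setequal(all_cand$drug_id, c("A", "C", "D", "E"))
  # one-drug library
  solo <- drug_library(list(drug_record("Z", associations = c(p01 = 200),
                                        fingerprint = fingerprint(1, 64))),
                       ppi_network(sprintf("p%02d", 1:20), NULL))
  expect_equal(nrow(candidate_substitutes("Z", solo)), 0L)
})

test_that("augment_pair substitutes both slots and transfers labels", {
  lib <- make_test_library()
  inst <- synergy_table("A", "B", "CL1", "synergy")
  aug <- augment_pair(as.list(inst[1]), lib)
  # B-slot: A:C and A:E
  bslot <- aug[aug$slot == "b"]
  expect_setequal(paste(bslot$drug_a, bslot$drug_b), c("A C", "A E"))
  expect_true(all(aug$label == "synergy"))
  expect_true(all(aug$provenance == "augmented"))
  expect_true(all(aug$parent == "A|B|CL1"))
  # no passing candidates -> empty
  inst2 <- synergy_table("A", "D", "CL1", "antagonism")
  aug2 <- augment_pair(as.list(inst2[1]), lib,
                       dacs_min = 0.99, tc_max = 0.01)
  expect_equal(nrow(aug2), 0L)
})

test_that("augmentation suppresses collisions and conserves labels/provenance", {
  b <- small_bundle()
  aug <- augment_dataset(b$synergy, b$library)
  expect_gt(nrow(aug), 0)
  # label conservation against parents
  parent_label <- stats::setNames(b$synergy$label, b$synergy$id)
  expect_true(all(aug$label == parent_label[aug$parent]))
  # provenance closure
  expect_true(all(aug$parent %in% b$synergy$id))
  # no duplicate of an original unordered pair on the same cell line
  okey <- paste(pmin(b$synergy$drug_a, b$synergy$drug_b),
                pmax(b$synergy$drug_a, b$synergy$drug_b),
                b$synergy$cell_line)
  akey <- paste(pmin(aug$drug_a, aug$drug_b),
                pmax(aug$drug_a, aug$drug_b), aug$cell_line)
  expect_length(intersect(okey, akey), 0L)
  # no degenerate pairs
  expect_true(all(aug$drug_a != aug$drug_b))
  # class-ratio stability within 10 percentage points
  expect_lt(abs(mean(aug$label == "synergy") -
                  mean(b$synergy$label == "synergy")), 0.10)
})

test_that("drug libraries load from TSV with either fingerprint source", {
  b <- small_bundle()
  d <- tempfile(); dir.create(d)
  write_dataset(b, d)
  lib <- read_drug_library(file.path(d, "drug_targets.tsv"), b$ppi,
                           fingerprints_path = file.path(d, "drug_fingerprints.tsv"))
  expect_setequal(names(lib$drugs), names(b$library$drugs))
  expect_identical(lib$fingerprints, b$library$fingerprints)
  # SMILES-backed mode
  smi <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.table::data.table(
    drug_id = names(b$library$drugs)[1:3],
    smiles = c("CCO", "c1ccccc1", "CC(=O)O")), smi, sep = "\t")
  tg2 <- tempfile(fileext = ".tsv")
  assoc <- data.table::fread(file.path(d, "drug_targets.tsv"))
  data.table::fwrite(assoc[assoc$drug_id %in% names(b$library$drugs)[1:3]],
                     tg2, sep = "\t")
  lib2 <- read_drug_library(tg2, b$ppi, smiles_path = smi, fp_width = 128L)
  expect_equal(length(lib2$drugs), 3L)
  expect_identical(lib2$fingerprints[[1]],
                   fingerprint_from_smiles("CCO", width = 128L))
})

test_that("synergy tables round-trip through TSV", {
  b <- small_bundle()
  aug <- augment_dataset(b$synergy[1:10], b$library)
  f <- tempfile(fileext = ".tsv")
  write_synergy_table(aug, f)
  back <- read_synergy_table(f)
  expect_equal(as.data.frame(back), as.data.frame(aug))
  expect_error(synergy_table("X", "X", "CL", "synergy"), "degenerate")
  expect_error(synergy_table("X", "Y", "CL", "maybe"), "label")
})
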