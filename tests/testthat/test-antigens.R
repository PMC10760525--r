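mk_proteomes <- function() {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref_seq <- paste(sample(aa, 300L, replace = TRUE), collapse = "")
  ref <- data.table::data.table(protein_id = "REF1", gene_id = "G1",
                                sequence = ref_seq)
  te_prot <- paste(sample(aa, 200L, replace = TRUE), collapse = "")
  ranges_te <- cbind(start = 1L, end = 120L)
  novel <- data.table::data.table(
    sequence = te_prot, gene_id = "NG1", tx_id = "TX_TE",
    class = "unannotated_coding", te_ranges = list(ranges_te))
  custom <- build_custom_proteome(novel, ref)
  list(ref = ref, custom = custom, ref_seq = ref_seq, te_prot = te_prot)
}

test_that("peptides classify canonical / TE / non-TE / unmatched correctly", {
  px <- mk_proteomes()
  canon <- substr(px$ref_seq, 40L, 48L)
  in_te <- substr(px$te_prot, 50L, 58L)
  out_te <- substr(px$te_prot, 150L, 158L)
  ghost <- "WWWWWWWWW"
  out <- classify_peptide(c(canon, in_te, out_te, ghost), px$ref, px$custom)
  expect_equal(out$category, c("canonical", "noncanonical_te",
                               "noncanonical_non_te", "unmatched"))
  expect_equal(out$n_sources[4], 0L)
  expect_true(grepl("NG1_NP_1", out$source_proteins[2]))
})

test_that("a peptide straddling the TE boundary still counts as TE-coded", {
  px <- mk_proteomes()
  straddle <- substr(px$te_prot, 115L, 123L)   # overlaps residues 115..120
  out <- classify_peptide(straddle, px$ref, px$custom)
  expect_equal(out$category, "noncanonical_te")
})

test_that("conservative multi-source rule: one non-TE source demotes the call", {
  px <- mk_proteomes()
  in_te <- substr(px$te_prot, 50L, 58L)
  ## add a second novel protein containing the same peptide outside any
  ## TE range
  extra <- data.table::data.table(
    sequence = paste0(strrep("A", 30L), in_te, strrep("C", 30L)),
    gene_id = "NG2", tx_id = "TX_PLAIN", class = "unannotated_coding")
  custom2 <- build_custom_proteome(
    data.table::rbindlist(list(
      data.table::data.table(sequence = px$te_prot, gene_id = "NG1",
                             tx_id = "TX_TE", class = "unannotated_coding",
                             te_ranges = list(cbind(start = 1L, end = 120L))),
      extra), fill = TRUE), px$ref)
  out <- classify_peptide(in_te, px$ref, custom2)
  expect_equal(out$category, "noncanonical_non_te")
  expect_equal(out$n_sources, 2L)
})

test_that("peptide validation rejects short or non-amino-acid input", {
  px <- mk_proteomes()
  expect_error(classify_peptide("SHORT", px$ref, px$custom), "8 aa")
  expect_error(classify_peptide("ACDEFGHIB", px$ref, px$custom), "alphabet")
})

test_that("expression attribution sums encoding transcripts and TE share", {
  px <- mk_proteomes()
  recs <- classify_peptide(substr(px$te_prot, 50L, 58L), px$ref, px$custom)
  expr <- data.table::data.table(
    tx_id = c("TX_TE", "TX_OTHER"),
    tpm_control = c(0, 5), tpm_treated = c(14, 5),
    is_te_transcript = c(TRUE, FALSE))
  out <- peptide_expression(recs, px$custom, expr)
  expect_equal(out$tpm_treated, 14)
  expect_equal(out$tpm_control, 0)
  expect_equal(out$te_fraction, 1)
})

test_that("the drug-induced TE antigen rule applies all four conditions", {
  flag <- function(...) call_drug_induced_te_antigen(...)
  ## detected only under treatment, 95% TE, 14 vs 0 TPM: flagged
  expect_true(flag(TRUE, FALSE, 14, 0, 0.95))
  ## TE share at or below 0.9 fails (strict bound)
  expect_false(flag(TRUE, FALSE, 14, 0, 0.85))
  expect_false(flag(TRUE, FALSE, 14, 0, 0.9))
  expect_true(flag(TRUE, FALSE, 14, 0, 0.91))
  ## fold at or below 10 fails (strict bound)
  expect_false(flag(TRUE, FALSE, 8, 1, 0.95))
  expect_false(flag(TRUE, FALSE, 10, 1, 0.95))
  expect_true(flag(TRUE, FALSE, 10.1, 1, 0.95))
  ## detection pattern must be treated-only
  expect_false(flag(TRUE, TRUE, 14, 0.1, 0.95))
  expect_false(flag(FALSE, FALSE, 0, 0, 0.95))
  ## detected but unexpressed is inconsistent
  expect_error(flag(TRUE, FALSE, 0, 0, 0.95), "inconsistent")
})

test_that("raising the TE-share or fold thresholds never adds antigens", {
  set.seed(33)
  n <- 60L
  det_t <- rep(TRUE, n)
  det_c <- sample(c(TRUE, FALSE), n, replace = TRUE)
  tpm_t <- stats::runif(n, 0.5, 30)
  tpm_c <- sample(c(0, 0.3, 2), n, replace = TRUE)
  tf <- stats::runif(n)
  base <- call_drug_induced_te_antigen(det_t, det_c, tpm_t, tpm_c, tf,
                                       0.9, 10)
  tighter_tf <- call_drug_induced_te_antigen(det_t, det_c, tpm_t, tpm_c, tf,
                                             0.95, 10)
  tighter_fold <- call_drug_induced_te_antigen(det_t, det_c, tpm_t, tpm_c,
                                               tf, 0.9, 20)
  expect_true(all(!tighter_tf | base))
  expect_true(all(!tighter_fold | base))
})

test_that("antigen tallies are deterministic and permutation-invariant", {
  empty <- summarize_antigens(data.table::data.table(category = character()))
  expect_true(all(empty$n == 0L))
  recs <- data.table::data.table(
    category = c(rep("canonical", 3L), "noncanonical_te"),
    detected_control = c(TRUE, TRUE, FALSE, FALSE),
    detected_treated = TRUE)
  tal <- summarize_antigens(recs)
  expect_equal(tal[category == "canonical", n], 3L)
  expect_equal(tal[category == "noncanonical_te", n], 1L)
  expect_equal(tal[category == "noncanonical_te", n_treated], 1L)
  expect_identical(tal, summarize_antigens(recs[c(4, 2, 1, 3)]))
})

test_that("classification is independent of proteome row order", {
  px <- mk_proteomes()
  peps <- c(substr(px$ref_seq, 10L, 18L), substr(px$te_prot, 60L, 68L))
  a <- classify_peptide(peps, px$ref, px$custom)
  b <- classify_peptide(peps, px$ref[seq(nrow(px$ref), 1L)],
                        px$custom[seq(nrow(px$custom), 1L)])
  expect_equal(a$category, b$category)
})
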