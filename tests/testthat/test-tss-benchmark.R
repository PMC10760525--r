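mk_gtss_models <- function() {
  transcript_models(
    tx_id = c("T1", "T2", "T3", "T4"),
    gene_id = c("G1", "G2", "G3", "G4"),
    chrom = "chr1", strand = c("+", "+", "-", "+"),
    exons = list(exon_matrix(c(1000L, 1400L), c(1200L, 1600L)),
                 exon_matrix(c(5000L, 5300L), c(5200L, 5500L)),
                 exon_matrix(c(8000L, 8400L), c(8200L, 8600L)),
                 exon_matrix(9000L, 9400L)),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA"))
}

expr_tbl <- function(...) {
  v <- c(...)
  data.table::data.table(tx_id = names(v), tpm = unname(v))
}

test_that("active TSSs require both quantifiers, coding biotype, and length", {
  models <- mk_gtss_models()
  e1 <- expr_tbl(T1 = 2, T2 = 2, T3 = 100, T4 = 100)
  e2 <- expr_tbl(T1 = 2, T2 = 0.5, T3 = 100, T4 = 100)
  act <- define_active_gtss(models, e1, e2)
  ## T2 fails the second quantifier, T4 is noncoding
  expect_equal(sort(act$tx_id), c("T1", "T3"))
  expect_equal(act[tx_id == "T1", pos], 1000L)
  expect_equal(act[tx_id == "T3", pos], 8599L)

  long_models <- data.table::copy(models)
  crit <- active_gtss_criteria(transcript_length_range = c(300, 350))
  act_len <- define_active_gtss(long_models, e1, e1, crit)
  expect_equal(nrow(act_len), 0L)  # all planted transcripts are 400 bp
})

test_that("transcripts missing from expression count as 0 TPM with a warning", {
  models <- mk_gtss_models()
  e_partial <- expr_tbl(T1 = 5)
  w <- testthat::capture_warnings(
    act <- define_active_gtss(models, e_partial, e_partial))
  expect_match(w, "0 TPM", all = TRUE)
  expect_length(w, 2L)   # once per quantifier table
  expect_equal(act$tx_id, "T1")
})

test_that("identical TSS positions collapse keeping the maximum TPM", {
  models <- transcript_models(
    tx_id = c("A1", "A2"), gene_id = "G", chrom = "chr1", strand = "+",
    exons = list(exon_matrix(c(100L, 300L), c(200L, 600L)),
                 exon_matrix(c(100L, 350L), c(200L, 650L))))
  e <- expr_tbl(A1 = 2, A2 = 9)
  act <- define_active_gtss(models, e, e)
  expect_equal(nrow(act), 1L)
  expect_equal(act$tpm, 9)
})

mk_peak <- function(start, end, strand = "+", chrom = "chr1")
  data.table::data.table(chrom = chrom, start = start, end = end,
                         strand = strand,
                         dominant_pos = as.integer((start + end) / 2))

test_that("the 200-bp tolerance window bounds detection exactly", {
  gtss <- data.table::data.table(chrom = "chr1", pos = 5000L, strand = "+")
  exact <- benchmark_peaks(mk_peak(5000L, 5001L), gtss)
  expect_equal(exact$recall, 1)
  expect_equal(exact$precision, 1)
  expect_equal(exact$f_score, 1)

  ## peak edge 150 bp away: inside the window
  expect_equal(benchmark_peaks(mk_peak(5151L, 5160L), gtss)$recall, 1)
  ## 250 bp away: outside
  near_miss <- benchmark_peaks(mk_peak(5251L, 5260L), gtss)
  expect_equal(near_miss$recall, 0)
  expect_equal(near_miss$precision, 0)
  ## boundary: expanded peak [start-200, end+200) must contain the TSS
  expect_equal(benchmark_peaks(mk_peak(5200L, 5210L), gtss)$recall, 1)
  expect_equal(benchmark_peaks(mk_peak(5201L, 5210L), gtss, 200L)$recall, 0)
  ## opposite strand never matches
  expect_equal(benchmark_peaks(mk_peak(5000L, 5001L, "-"), gtss)$recall, 0)
  expect_error(benchmark_peaks(mk_peak(1L, 2L), gtss[0]), "empty")
})

test_that("recall is monotone in the tolerance window", {
  set.seed(9)
  gtss <- data.table::data.table(chrom = "chr1",
                                 pos = sort(sample(1:10000, 25)),
                                 strand = "+")
  peaks <- mk_peak(sort(sample(1:10000, 15)), NA)
  peaks[, end := start + 10L]
  r0 <- benchmark_peaks(peaks, gtss, tolerance = 0L)$recall
  r200 <- benchmark_peaks(peaks, gtss, tolerance = 200L)$recall
  expect_lte(r0, r200)
})

test_that("rediscovery needs a single CTSS with at least two reads in the window", {
  gtss <- data.table::data.table(chrom = "chr1", pos = 1000L, strand = "+")
  ctss_at <- function(pos, count, strand = "+")
    data.table::data.table(chrom = "chr1", pos = pos, strand = strand,
                           count = count)
  expect_equal(rediscovery_rate(gtss, ctss_at(1150L, 2L))$rate, 1)
  expect_equal(rediscovery_rate(gtss, ctss_at(1000L, 1L))$rate, 0)
  expect_equal(rediscovery_rate(gtss, ctss_at(1201L, 5L))$rate, 0)
  expect_equal(rediscovery_rate(gtss, ctss_at(1200L, 2L))$rate, 1)
  expect_equal(rediscovery_rate(gtss, ctss_at(1000L, 9L, strand = "-"))$rate, 0)
  expect_error(rediscovery_rate(gtss[0], ctss_at(1000L, 3L)), "empty")
})

test_that("stratified recall reports per-stratum values and NA for empty strata", {
  gtss <- data.table::data.table(
    chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L), strand = "+",
    mapp = c(0.1, 0.2, 0.9, 0.95))
  ## peaks detect only the high-mappability pair
  peaks <- mk_peak(c(3000L, 4000L), c(3001L, 4001L))
  out <- stratified_recall(peaks, gtss, column = "mapp",
                           breaks = c(0, 0.5, 1))
  expect_equal(out$recall, c(0, 1))
  all_det <- stratified_recall(mk_peak(c(1000L, 2000L, 3000L, 4000L),
                                       c(1001L, 2001L, 3001L, 4001L)),
                               gtss, column = "mapp", breaks = c(0, 0.5, 1))
  expect_equal(all_det$recall, c(1, 1))
  with_empty <- stratified_recall(peaks, gtss, column = "mapp",
                                  breaks = c(0, 0.5, 0.97, 1))
  expect_true(is.na(with_empty$recall[3]))
  expect_error(stratified_recall(peaks, gtss, column = "mapp",
                                 breaks = c(0, 0.6, 0.4, 1)), "increasing")
})

test_that("size-weighted stratum recalls reproduce the overall recall", {
  set.seed(31)
  gtss <- data.table::data.table(
    chrom = "chr1", pos = sort(sample(1:50000, 60)), strand = "+",
    tpm = stats::rexp(60, 0.2))
  peaks <- mk_peak(sort(sample(1:50000, 30)), NA)
  peaks[, end := start + 20L]
  bm <- benchmark_peaks(peaks, gtss)
  st <- stratified_recall(peaks, gtss, column = "tpm",
                          breaks = c(0, 1, 5, Inf))
  expect_equal(sum(st$n * st$recall, na.rm = TRUE) / sum(st$n), bm$recall)
})
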