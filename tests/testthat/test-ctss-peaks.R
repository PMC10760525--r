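test_that("CTSS extraction takes the strand-aware aligned 5' end", {
  plus <- mk_aln("p1", blocks = cbind(100L, 200L))
  out <- extract_ctss(plus)
  expect_equal(out$pos, 100L)
  expect_equal(out$count, 1L)

  minus <- mk_aln("m1", strand = "-", blocks = cbind(100L, 200L))
  expect_equal(extract_ctss(minus)$pos, 199L)

  multi <- data.table::rbindlist(list(
    mk_aln("a"), mk_aln("b"), mk_aln("c"),
    mk_aln("d", blocks = cbind(101L, 200L))))
  agg <- extract_ctss(multi)
  expect_equal(agg[order(pos), .(pos, count)],
               data.table::data.table(pos = c(100L, 101L), count = c(3L, 1L)))
})

test_that("paraclu handles degenerate inputs", {
  empty <- extract_ctss(lrcage:::empty_alignments())
  expect_equal(nrow(paraclu_cluster(empty)), 0L)
  single <- data.table::data.table(chrom = "c", pos = 10L, strand = "+",
                                   count = 5L)
  cl <- paraclu_cluster(single)
  expect_equal(cl$start, 10L)
  expect_equal(cl$end, 11L)
  expect_equal(cl$total_count, 5L)
})

test_that("paraclu equals the brute-force oracle on a specific profile", {
  pos <- c(1L, 3L, 200L, 202L)
  cnt <- c(10L, 8L, 2L, 2L)
  expect_paraclu_matches_oracle(pos, cnt)
  ## and the filtered cluster set is sane under defaults
  ctss <- data.table::data.table(chrom = "c", pos = pos, strand = "+",
                                 count = cnt)
  cl <- paraclu_cluster(ctss)
  expect_true(all(cl$end - cl$start <= 500L))
  expect_true(all(cl$total_count >= 2L))
  expect_true(all(cl$max_density / cl$min_density >= 2 |
                    cl$min_density == 0))
})

test_that("paraclu equals the brute-force oracle on random profiles", {
  set.seed(101)
  for (r in 1:40) {
    n <- sample(1:25, 1)
    pos <- sort(sample(1:400, n))
    cnt <- sample(1:20, n, replace = TRUE)
    expect_paraclu_matches_oracle(pos, cnt)
  }
})

test_that("cluster counts never exceed CTSS totals, with equality unfiltered", {
  set.seed(7)
  ctss <- data.table::data.table(
    chrom = "c", strand = "+",
    pos = sort(sample(1:2000, 40)), count = sample(1:15, 40, replace = TRUE))
  full <- paraclu_cluster(ctss, min_stability = 1, max_length = 10000L,
                          min_count = 1L)
  expect_equal(sum(full$total_count), sum(ctss$count))
  filt <- paraclu_cluster(ctss)
  expect_lte(sum(filt$total_count), sum(ctss$count))
})

test_that("reported clusters never overlap within a strand", {
  ref <- std_reference()
  sim <- simulate_cage_reads(ref$truth, "LRCAGE", depth = 3L, noise = 0.4)
  ctss <- extract_ctss(deduplicate(sim$alignments))
  cl <- paraclu_cluster(ctss)
  by_grp <- split(cl, paste(cl$chrom, cl$strand))
  for (g in by_grp) {
    g <- g[order(start)]
    if (nrow(g) > 1L) expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
  }
})

## ---- cap filter -------------------------------------------------------

test_that("cap filter retains clusters at or above the 0.35 G fraction", {
  fx <- mk_cap_fixture(4L, 10L)
  res <- cap_signal_filter(fx$clusters, fx$aln, fx$genome, cutoff = 0.35)
  expect_equal(res$audit$cap_g_fraction, 0.4)
  expect_equal(nrow(res$kept), 1L)

  fx3 <- mk_cap_fixture(3L, 10L)
  res3 <- cap_signal_filter(fx3$clusters, fx3$aln, fx3$genome, cutoff = 0.35)
  expect_equal(res3$audit$cap_g_fraction, 0.3)
  expect_equal(nrow(res3$kept), 0L)
  expect_equal(res3$audit$decision, "discard")

  fx_all <- mk_cap_fixture(10L, 10L)
  expect_equal(cap_signal_filter(fx_all$clusters, fx_all$aln,
                                 fx_all$genome)$kept$cap_g_fraction, 1)
})

test_that("a templated upstream G does not count as cap evidence", {
  fx <- mk_cap_fixture(10L, 10L, genome_base = "G")
  res <- cap_signal_filter(fx$clusters, fx$aln, fx$genome)
  expect_equal(res$audit$cap_g_fraction, 0)
})

test_that("cap filter is monotone in the cutoff", {
  run <- std_run()
  aln <- deduplicate(simulate_cage_reads(run$truth, "LRCAGE", depth = 3L,
                                         noise = 0.3)$alignments)
  cl <- paraclu_cluster(extract_ctss(aln))
  kept_lo <- cap_signal_filter(cl, aln, run$truth$genome, cutoff = 0.35)$kept
  kept_hi <- cap_signal_filter(cl, aln, run$truth$genome, cutoff = 0.8)$kept
  key <- function(x) paste(x$chrom, x$start, x$end, x$strand)
  expect_true(all(key(kept_hi) %in% key(kept_lo)))
})

test_that("a cluster with no supporting reads is an input error", {
  fx <- mk_cap_fixture(2L, 4L)
  bad <- data.table::copy(fx$clusters)[, `:=`(start = 5000L, end = 5001L,
                                              dominant_pos = 5000L)]
  expect_error(cap_signal_filter(bad, fx$aln, fx$genome), "zero supporting")
})

## ---- annotation, consensus, fold change -------------------------------

test_that("peak categories follow the fixed priority order", {
  ann <- mk_tiny_annotation()
  pk <- function(pos, strand = "+")
    data.table::data.table(chrom = "chrT1", start = pos, end = pos + 1L,
                           strand = strand, dominant_pos = pos)
  expect_equal(annotate_peaks(pk(900L), ann)$category, "promoter")
  ## promoter is strand-aware: same point, opposite strand
  expect_equal(annotate_peaks(pk(700L, "-"), ann)$category, "intergenic")
  ## with a narrow promoter window the 5' UTR is exposed
  ann_narrow <- tx_annotation(ann$models, promoter_upstream = 500L,
                              promoter_downstream = 20L)
  expect_equal(annotate_peaks(pk(1050L), ann_narrow)$category, "utr5")
  expect_equal(annotate_peaks(pk(1950L), ann)$category, "other_exon")
  expect_equal(annotate_peaks(pk(1300L), ann)$category, "intron")
  expect_equal(annotate_peaks(pk(9000L), ann)$category, "intergenic")
})

test_that("an exonic hit outranks another transcript's intron", {
  models <- transcript_models(
    tx_id = c("T1", "T2"), gene_id = c("G1", "G2"), chrom = "chrT1",
    strand = "+",
    exons = list(exon_matrix(c(1000L, 3000L), c(1200L, 3200L)),
                 exon_matrix(c(900L, 4000L), c(950L, 4100L))))
  ann <- tx_annotation(models)
  ## 3100 is inside T1's internal exon and inside T2's intron
  pk <- data.table::data.table(chrom = "chrT1", start = 3100L, end = 3101L,
                               strand = "+", dominant_pos = 3100L)
  expect_equal(annotate_peaks(pk, ann)$category, "other_exon")
})

test_that("consensus merging unions overlapping same-strand peaks", {
  one <- data.table::data.table(chrom = "c", start = 100L, end = 150L,
                                strand = "+", total_count = 5L,
                                dominant_pos = 120L)
  two <- data.table::data.table(chrom = "c", start = 140L, end = 180L,
                                strand = "+", total_count = 7L,
                                dominant_pos = 160L)
  cons <- merge_consensus_peaks(list(a = one, b = two))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 180L)
  expect_equal(cons$count_a, 5L)
  expect_equal(cons$count_b, 7L)

  ident <- merge_consensus_peaks(list(a = one, b = one))
  expect_equal(nrow(ident), 1L)
  expect_equal(ident$count_a, ident$count_b)

  opp <- data.table::copy(one)[, strand := "-"]
  both <- merge_consensus_peaks(list(a = one, b = opp))
  expect_equal(nrow(both), 2L)
  expect_equal(sort(both$strand), c("+", "-"))
})

test_that("fold-change up-regulation uses pseudocount-normalised ratios", {
  cons <- data.table::data.table(chrom = "c", start = c(1L, 10L, 20L),
                                 end = c(2L, 11L, 21L), strand = "+")
  treated <- c(80L, 50L, 40L)
  control <- c(10L, 50L, 0L)
  ## pad totals to 1e6 with a balance row
  cons2 <- rbind(cons, data.table::data.table(chrom = "c", start = 90L,
                                              end = 91L, strand = "+"))
  t2 <- c(treated, 1e6L - sum(treated))
  c2 <- c(control, 1e6L - sum(control))
  res <- call_upregulated_peaks(cons2, t2, c2)
  expect_equal(res$fold[1], 81 / 11, tolerance = 1e-6)
  expect_true(res$upregulated[1])
  expect_equal(res$fold[2], 1, tolerance = 1e-3)
  expect_false(res$upregulated[2])
  ## control 0 with pseudocount 1: fold 41 on equal library totals
  expect_equal(res$fold[3], (41 / 1e6) / (1 / 1e6) *
                 sum(c2) / sum(t2), tolerance = 1e-6)
  expect_true(res$upregulated[3])
  expect_error(call_upregulated_peaks(cons[3], 0L, 0L), "zero library")
})
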