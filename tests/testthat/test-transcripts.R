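test_that("5' support requires a same-strand peak within the slack", {
  pk <- data.table::data.table(chrom = "chrT1", start = 1000L, end = 1010L,
                               strand = "+")
  inside <- mk_model("in", exons = exon_matrix(c(1005L, 1400L),
                                               c(1200L, 1600L)))
  far <- mk_model("far", exons = exon_matrix(c(2500L, 2900L),
                                             c(2700L, 3100L)))
  opp <- transcript_models("opp", "G", "chrT1", "-",
                           list(exon_matrix(c(700L, 950L), c(800L, 1006L))))
  expect_equal(filter_five_prime_support(inside, pk)$tx_id, "in")
  expect_equal(nrow(filter_five_prime_support(far, pk)), 0L)
  ## opp's TSS (1005) sits inside the peak interval but on the other strand
  expect_equal(nrow(filter_five_prime_support(opp, pk)), 0L)
})

test_that("5' support is monotone in slack and slack 0 is containment", {
  pk <- data.table::data.table(chrom = "chrT1", start = 1000L, end = 1010L,
                               strand = "+")
  at_edge <- mk_model("edge", exons = exon_matrix(c(1040L, 1400L),
                                                  c(1200L, 1600L)))
  expect_equal(nrow(filter_five_prime_support(at_edge, pk, slack = 0L)), 0L)
  expect_equal(nrow(filter_five_prime_support(at_edge, pk, slack = 50L)), 1L)
  inside <- mk_model("in", exons = exon_matrix(c(1005L, 1400L),
                                               c(1200L, 1600L)))
  expect_equal(nrow(filter_five_prime_support(inside, pk, slack = 0L)), 1L)
})

## reference for novelty tests: two + transcripts of one gene sharing
## exon [1000,1200) but with different downstream junctions, and one -
## gene
mk_novelty_annotation <- function() {
  models <- transcript_models(
    tx_id = c("TXA", "TXA2", "TXB"),
    gene_id = c("GA", "GA", "GB"),
    chrom = "chrT1", strand = c("+", "+", "-"),
    exons = list(
      exon_matrix(c(1000L, 1400L, 1800L), c(1200L, 1600L, 2100L)),
      exon_matrix(c(1000L, 1700L, 1800L), c(1200L, 1750L, 2100L)),
      exon_matrix(c(5000L, 5500L), c(5300L, 5700L))))
  tx_annotation(models)
}

test_that("novelty classes follow the splice-chain rules", {
  ann <- mk_novelty_annotation()
  classify1 <- function(m) classify_novelty(m, ann)$novelty_class
  ## exact chain match
  expect_equal(classify1(mk_model("known", exons = exon_matrix(
    c(1000L, 1400L, 1800L), c(1200L, 1600L, 2100L)), gene_id = "GA")),
    "known")
  ## contiguous sub-chain (second junction of TXA only)
  expect_equal(classify1(mk_model("ism", exons = exon_matrix(
    c(1450L, 1800L), c(1600L, 1900L)))), "ISM")
  ## both junctions known individually, chain novel (TXA J1 + TXA2 J2)
  expect_equal(classify1(mk_model("nic", exons = exon_matrix(
    c(1100L, 1400L, 1800L), c(1200L, 1750L, 1900L)))), "NIC")
  ## novel junction within the gene
  expect_equal(classify1(mk_model("nnc", exons = exon_matrix(
    c(1000L, 1500L), c(1200L, 1650L)))), "NNC")
  ## overlaps GA on the opposite strand only
  expect_equal(classify1(transcript_models(
    "anti", "X", "chrT1", "-",
    list(exon_matrix(c(1000L, 1500L), c(1200L, 1650L))))), "antisense")
  ## no gene overlap
  expect_equal(classify1(mk_model("inter", exons = exon_matrix(
    c(9000L, 9500L), c(9200L, 9700L)))), "intergenic")
  ## mono-exonic inside a gene
  expect_equal(classify1(mk_model("geno", exons = exon_matrix(1050L, 1150L))),
               "genomic")
  expect_equal(classify1(mk_model("mono_inter",
                                  exons = exon_matrix(20000L, 20200L))),
               "intergenic")
})

test_that("novelty classification is deterministic and order-independent", {
  ann <- mk_novelty_annotation()
  set.seed(12)
  models <- data.table::rbindlist(lapply(1:12, function(i) {
    s1 <- sample(seq(900L, 1500L, by = 10L), 1)
    mk_model(sprintf("m%02d", i),
             exons = exon_matrix(c(s1, s1 + 400L), c(s1 + 150L, s1 + 600L)))
  }))
  a <- classify_novelty(models, ann)
  b <- classify_novelty(models[rev(seq_len(nrow(models)))], ann)
  expect_equal(a[order(tx_id), novelty_class],
               b[order(tx_id), novelty_class])
  expect_true(all(a$novelty_class %in%
                    c("known", "ISM", "NIC", "NNC", "antisense",
                      "intergenic", "genomic")))
})

test_that("TPM has no length normalisation and sums to one million", {
  asn <- data.table::data.table(tx_id = c(rep("A", 5L), rep("B", 5L)))
  q <- quantify_tpm(asn)
  expect_equal(q$tpm, c(5e5, 5e5))
  models <- data.table::data.table(tx_id = c("A", "B"))
  q2 <- quantify_tpm(data.table::data.table(tx_id = "A"), models)
  expect_equal(q2[tx_id == "A", tpm], 1e6)
  expect_equal(q2[tx_id == "B", tpm], 0)
  expect_equal(sum(q$tpm), 1e6)
  expect_error(quantify_tpm(asn[0], models), "zero total")
})

test_that("LTR context follows proviral > genic > unannotated precedence", {
  te <- data.table::data.table(
    te_id = c("ltr1", "ltr2", "ltr3"), chrom = "chrT1",
    start = c(1000L, 4000L, 7000L), end = c(1700L, 4700L, 7700L),
    strand = "+", subfamily = "LTR12C", family = "ERV1",
    class_name = "LTR", substitutions = 1L, insertions = 0L)
  proviral <- data.table::data.table(locus_id = "hv", chrom = "chrT1",
                                     start = 1000L, end = 2600L,
                                     strand = "+", clade = "HERV9")
  host <- transcript_models("host", "GH", "chrT1", "+",
                            list(exon_matrix(c(3900L, 5600L),
                                             c(4100L, 5900L))))
  ann <- tx_annotation(host)
  mods <- transcript_models(
    tx_id = c("pv", "genic", "unann", "none"),
    gene_id = "N", chrom = "chrT1", strand = "+",
    exons = list(
      exon_matrix(c(1100L, 1900L), c(1400L, 2200L)),
      exon_matrix(c(4100L, 4900L), c(4400L, 5200L)),
      exon_matrix(c(7100L, 7900L), c(7400L, 8200L)),
      exon_matrix(c(9100L, 9900L), c(9400L, 10200L))))
  out <- tag_te_context(mods, te, proviral, ann)
  expect_equal(out$te_5prime_class, c("LTR", "LTR", "LTR", "none"))
  expect_equal(out$context, c("proviral_HERV", "genic", "unannotated",
                              "not_applicable"))
})

test_that("drug induction needs >=1 TPM treated and exactly 0 control", {
  expect_true(call_drug_induced(1.2, 0))
  expect_true(call_drug_induced(1.0, 0))
  expect_false(call_drug_induced(0.8, 0))
  expect_false(call_drug_induced(5, 0.1))
  expect_equal(call_drug_induced(c(2, 0.5, 3), c(0, 0, 1)),
               c(TRUE, FALSE, FALSE))
  expect_error(call_drug_induced(-1, 0), "nonnegative")
})
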