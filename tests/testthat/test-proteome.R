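## deterministic coding sequences for construction-based checks
mk_cds <- function(n_aa, seed) {
  set.seed(seed)
  codons <- lrcage:::sense_codons()
  paste0("ATG", paste(sample(codons, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

test_that("the 100-aa ORF floor is an exact boundary", {
  cds99 <- mk_cds(99L, 1)
  cds100 <- mk_cds(100L, 1)
  expect_null(find_longest_orf(cds99, min_aa = 100L))
  orf <- find_longest_orf(cds100, min_aa = 100L)
  expect_equal(orf$n_aa, 100L)
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, nchar(cds100))
})

test_that("the longest qualifying ORF wins, ties to the 5'-most start", {
  ## the spacer carries stop codons in all three frames so the two
  ## planted ORFs cannot read through each other
  spacer <- strrep("TAATAATAAC", 3L)
  seq <- paste0(mk_cds(120L, 2), spacer, mk_cds(150L, 3))
  orf <- find_longest_orf(seq, min_aa = 100L)
  expect_equal(orf$n_aa, 150L)
  expect_equal(orf$start, 3L * 121L + nchar(spacer))
  ## an ORF running off the 3' end does not qualify
  headless <- paste0("ATG", strrep("GCT", 150L))  # no stop codon
  expect_null(find_longest_orf(headless, min_aa = 100L))
})

test_that("ORF detection equals the exhaustive codon-walk oracle", {
  set.seed(21)
  for (r in 1:60) {
    s <- random_dna_str(sample(500:2000, 1))
    min_aa <- sample(c(15L, 40L, 100L), 1)
    a <- find_longest_orf(s, min_aa)
    b <- oracle_longest_orf(s, min_aa)
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$start, b$start)
      expect_equal(a$end, b$end)
      expect_equal(a$protein, b$protein)
    }
  }
})

test_that("the NMD rule drops stops >50 nt upstream of the last junction", {
  ## two exons, transcript length 500, last junction at 300
  exons <- exon_matrix(c(0L, 400L), c(300L, 600L))
  orf_at <- function(end) list(start = 0L, end = end, n_aa = (end %/% 3L) - 1L)
  ## stop codon starts at end-3; distance 300-(end-3)
  expect_false(nmd_filter(exons, "+", orf_at(240L)))  # 63 nt upstream
  expect_true(nmd_filter(exons, "+", orf_at(253L)))   # exactly 50 nt
  expect_false(nmd_filter(exons, "+", orf_at(252L)))  # 51 nt
  expect_true(nmd_filter(exons, "+", orf_at(480L)))   # stop in last exon
  mono <- exon_matrix(0L, 600L)
  expect_true(nmd_filter(mono, "+", orf_at(120L)))
  expect_error(nmd_filter(exons, "+", orf_at(650L)), "outside")
})

test_that("three-frame peptides equal the codon-walk oracle", {
  ## 60 nt can encode at most 20 aa: empty at the 25-aa floor
  expect_equal(nrow(three_frame_peptides(random_dna_str(60L))), 0L)
  ## stops in every frame within any 25-codon window: empty
  stopper <- strrep("TAATAATAAC", 12L)
  expect_equal(nrow(three_frame_peptides(stopper)), 0L)
  ## a planted stop-free 30-aa stretch in frame 1 (offset 1); other
  ## frames may emit their own stretches, but the planted peptide must
  ## come back verbatim from its frame
  set.seed(5)
  core <- substr(mk_cds(40L, 6), 4L, 3L + 90L)  # 30 sense codons
  planted <- paste0("C", "TAA", core, "TAG", strrep("TAATAATAAC", 10L))
  out <- three_frame_peptides(planted, min_aa = 25L)
  hit <- out[peptide == lrcage:::translate_dna(core)]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$frame, 1L)
  set.seed(22)
  for (r in 1:40) {
    s <- random_dna_str(sample(500:2000, 1))
    expect_equal(sort(three_frame_peptides(s, 25L)$peptide),
                 oracle_three_frame(s, 25L))
  }
})

test_that("per-frame peptide concatenation reproduces the frame translation", {
  set.seed(23)
  s <- random_dna_str(900L)
  out <- three_frame_peptides(s, min_aa = 1L)
  for (f in 0:2) {
    full <- lrcage:::translate_dna(substr(s, f + 1L, nchar(s)))
    expect_equal(paste(out[frame == f, peptide], collapse = ""),
                 gsub("*", "", full, fixed = TRUE))
  }
})

test_that("TE-coded residue ranges map genomic TE overlap through codons", {
  ## + strand, exons [0,300) and [500,800); TE covers [0,250)
  exons <- exon_matrix(c(0L, 500L), c(300L, 800L))
  te <- data.table::data.table(te_id = "t", chrom = "c", start = 0L,
                               end = 250L, strand = "+", subfamily = "s",
                               family = "f", class_name = "LTR",
                               substitutions = 0L, insertions = 0L)
  orf <- list(start = 30L, end = 330L)   # 99 aa + stop
  r <- te_coded_ranges(exons, "+", "c", orf, te)
  expect_equal(nrow(r), 1L)
  expect_equal(unname(r[1, "start"]), 1L)
  ## codon of residue 74 spans [249,252): still TE-touched; residue 75 is not
  expect_equal(unname(r[1, "end"]), 74L)
})

test_that("protein classes follow the reference-overlap decision order", {
  ref <- data.table::data.table(
    protein_id = c("P1", "P2"), gene_id = c("G1", "G2"),
    sequence = c(strrep("ACDEFGHIKL", 20L), strrep("MNPQRSTVWY", 15L)))
  p1 <- ref$sequence[1]
  expect_equal(classify_protein(p1, ref, "G1"), "annotated")
  expect_equal(classify_protein(substr(p1, 51L, 200L), ref, "G1"),
               "truncated")
  ## 22 novel residues prepended to a full reference protein
  novel22 <- strrep("W", 22L)
  expect_equal(classify_protein(paste0(novel22, p1), ref, "G1"), "chimeric")
  ## novel tail after a truncated reference block
  expect_equal(classify_protein(paste0(substr(p1, 1L, 80L), strrep("W", 30L)),
                                ref, "G1"), "chimeric_truncated")
  ## reference prefix + novel insertion + reference suffix
  expect_equal(classify_protein(
    paste0(substr(p1, 1L, 40L), strrep("W", 15L), substr(p1, 150L, 200L)),
    ref, "G1"), "novel_internal")
  ## no shared block with the same gene
  expect_equal(classify_protein(strrep("WYWV", 30L), ref, "G1",
                                overlaps_cds = TRUE), "out_of_frame")
  expect_equal(classify_protein(strrep("WYWV", 30L), ref, "G1",
                                overlaps_cds = FALSE), "unannotated_coding")
  ## classification ignores reference table order
  expect_equal(classify_protein(substr(p1, 51L, 200L), ref[2:1], "G1"),
               "truncated")
})

test_that("the custom proteome merges, deduplicates, and numbers novels", {
  ref <- data.table::data.table(
    protein_id = c("P1", "P2"), gene_id = c("G1", "G2"),
    sequence = c(strrep("ACDEFGHIKL", 20L), strrep("MNPQRSTVWY", 15L)))
  none <- build_custom_proteome(
    data.table::data.table(sequence = character(), gene_id = character(),
                           tx_id = character(), class = character()), ref)
  expect_equal(none$protein_id, ref$protein_id)
  expect_equal(none$sequence, ref$sequence)

  novel <- data.table::data.table(
    sequence = c(strrep("AC", 60L), strrep("DE", 60L), ref$sequence[1]),
    gene_id = c("G9", "G9", "G1"),
    tx_id = c("t1", "t2", "t3"),
    class = "unannotated_coding")
  merged <- build_custom_proteome(novel, ref)
  expect_equal(sum(merged$source == "novel"), 2L)  # exact duplicate dropped
  expect_setequal(merged[source == "novel", protein_id],
                  c("G9_NP_1", "G9_NP_2"))
  expect_false(any(duplicated(merged$protein_id)))
})
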