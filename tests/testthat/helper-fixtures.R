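## Shared fixtures, generated once per test session and cached.
.lrcage_test_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .lrcage_test_cache)) {
    assign(key, fn(), envir = .lrcage_test_cache)
  }
  get(key, envir = .lrcage_test_cache)
}

## Standard study-condition fixture: 20 genes, 5 cryptic TE promoters,
## one duplicated low-mappability segment, fixed seed.
std_spec <- function() toy_genome_spec(seed = 1L)

std_reference <- function() cached("reference", function()
  make_toy_reference(std_spec()))

std_run <- function() cached("run", function() run_pipeline())

## Small fixture for quick unit checks.
small_reference <- function() cached("small_reference", function()
  make_toy_reference(toy_genome_spec(
    chrom_length = 25000L, n_genes = 5L, n_te_elements = 8L,
    n_cryptic_te_promoters = 3L, duplicated_segment_length = 1500L,
    seed = 7L)))

## Hand-built alignment table row.
mk_aln <- function(read_id, chrom = "chrT1", strand = "+",
                   blocks = cbind(100L, 200L), clip5 = 0L, clip3 = 0L,
                   clip5_seq = "", umi = "AAAAAAAA", mapq = 60L,
                   is_primary = TRUE, is_supplementary = FALSE,
                   is_unique = TRUE, seq = "") {
  dt <- data.table::data.table(
    read_id = read_id, chrom = chrom, strand = strand,
    clip5 = clip5, clip3 = clip3, clip5_seq = clip5_seq, clip3_seq = "",
    umi = umi, mapq = mapq, is_primary = is_primary,
    is_supplementary = is_supplementary, is_unique = is_unique, seq = seq)
  dt$blocks <- list(blocks)
  dt
}

## A one-cluster cap-signal fixture: n_total reads at position 100 of
## which the first n_g carry a soft-clipped unencoded G; the genomic
## base upstream of the start is configurable.
mk_cap_fixture <- function(n_g, n_total, genome_base = "T") {
  genome <- c(chrT1 = paste0(strrep("A", 99L), genome_base,
                             strrep("C", 300L)))
  aln <- data.table::rbindlist(lapply(seq_len(n_total), function(i) {
    has_g <- i <= n_g
    mk_aln(sprintf("r%02d", i), blocks = cbind(100L, 200L),
           clip5 = as.integer(has_g), clip5_seq = if (has_g) "G" else "",
           umi = sprintf("%08d", i))
  }))
  clusters <- data.table::data.table(
    chrom = "chrT1", start = 100L, end = 101L, strand = "+",
    total_count = n_total, dominant_pos = 100L, dominant_count = n_total,
    min_density = 1, max_density = Inf)
  list(genome = genome, aln = aln, clusters = clusters)
}

## Two-gene reference annotation on one toy chromosome, hand-built for
## classification tests. Gene A: + strand, exons [1000,1200) [1400,1600)
## [1800,2100); gene B: - strand, exons [5000,5300) [5500,5700).
mk_tiny_annotation <- function() {
  models <- transcript_models(
    tx_id = c("TXA", "TXB"),
    gene_id = c("GA", "GB"),
    chrom = "chrT1",
    strand = c("+", "-"),
    exons = list(
      exon_matrix(c(1000L, 1400L, 1800L), c(1200L, 1600L, 2100L)),
      exon_matrix(c(5000L, 5500L), c(5300L, 5700L))),
    cds_start = c(1100L, 5100L), cds_end = c(2000L, 5600L))
  tx_annotation(models)
}

mk_model <- function(tx_id, chrom = "chrT1", strand = "+", exons,
                     gene_id = "GX", biotype = "protein_coding") {
  transcript_models(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                    strand = strand, exons = list(exons),
                    biotype = biotype)
}
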