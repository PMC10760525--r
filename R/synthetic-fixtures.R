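#' Specification for a toy reference
#'
#' Describes the synthetic genome used to exercise the whole pipeline:
#' a small multi-chromosome genome carrying annotated multi-exon
#' protein-coding genes, a catalog of transposable elements (TEs), a
#' configurable number of cryptic TE promoters driving unannotated
#' transcripts, and one pair of identical (verbatim-duplicated)
#' segments that create a low-mappability region. The same seed always
#' regenerates byte-identical output.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp; must be at least ten
#'   times `duplicated_segment_length`.
#' @param n_genes Number of annotated protein-coding genes (>= 2).
#' @param n_te_elements Total TE elements in the catalog (>=
#'   `n_cryptic_te_promoters`).
#' @param n_cryptic_te_promoters TE elements that carry a planted
#'   cryptic promoter driving an unannotated transcript.
#' @param duplicated_segment_length Length of the segment copied
#'   verbatim to a second locus.
#' @param seed Integer seed; fully determines all outputs.
#' @return An object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(n_chroms = 2L, chrom_length = 60000L,
                            n_genes = 20L, n_te_elements = 24L,
                            n_cryptic_te_promoters = 5L,
                            duplicated_segment_length = 2000L, seed = 1L) {
  assert_count(n_chroms, "n_chroms")
  assert_count(chrom_length, "chrom_length")
  assert_count(n_genes, "n_genes", min = 2L)
  assert_count(n_te_elements, "n_te_elements")
  assert_count(n_cryptic_te_promoters, "n_cryptic_te_promoters", min = 0L)
  assert_count(duplicated_segment_length, "duplicated_segment_length")
  assert_that(chrom_length >= 10L * duplicated_segment_length,
              "chrom_length must be >= 10 * duplicated_segment_length")
  assert_that(n_te_elements >= n_cryptic_te_promoters,
              "n_te_elements must be >= n_cryptic_te_promoters")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 n_te_elements = as.integer(n_te_elements),
                 n_cryptic_te_promoters = as.integer(n_cryptic_te_promoters),
                 duplicated_segment_length = as.integer(duplicated_segment_length),
                 seed = as.integer(seed)),
            class = "toy_genome_spec")
}

## Subfamily palette: (subfamily, family, class); the first entries are
## the evolutionarily young promoters the cryptic units cycle through.
te_palette <- function() {
  data.table(
    subfamily = c("LTR12C", "LTR12E", "L1HS", "SVA_F", "L1PA2",
                  "AluY", "AluSx", "L2a", "MIR", "MLT1K", "LTR7", "L1M5"),
    family = c("ERV1", "ERV1", "L1", "SVA", "L1",
               "Alu", "Alu", "L2", "MIR", "ERVL-MaLR", "ERVK", "L1"),
    class_name = c("LTR", "LTR", "LINE", "SVA", "LINE",
                   "SINE", "SINE", "LINE", "SINE", "LTR", "LTR", "LINE"),
    young = c(rep(TRUE, 6L), rep(FALSE, 6L))
  )
}

aa_letters <- function() {
  setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds <- function(n_aa) {
  codons <- sense_codons()
  paste0("ATG", paste(sample(codons, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

## 5' UTR from {C,G,T} only: an A-free UTR can never contain an ATG, so
## the planted CDS stays the 5'-most ORF in its frame.
random_utr5 <- function(n) {
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_sequence <- function(genome, chrom, start0, seq) {
  s <- genome[[chrom]]
  substr(s, start0 + 1L, start0 + nchar(seq)) <- seq
  genome[[chrom]] <- s
  genome
}

## Write a spliced transcript sequence into the genome across an exon
## chain (transcript orientation -> genome orientation).
plant_transcript <- function(genome, chrom, exons, strand, tx_seq) {
  w <- exon_widths(exons)
  stopifnot(nchar(tx_seq) == sum(w))
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  off <- 0L
  for (e in ord) {
    piece <- substr(tx_seq, off + 1L, off + w[e])
    if (strand == "-") piece <- revcomp(piece)
    genome <- plant_sequence(genome, chrom, exons[e, 1L], piece)
    off <- off + w[e]
  }
  genome
}

## Force the genomic base immediately 5' of a TSS (in transcript
## orientation) to 'T' so an unencoded cap G can never match the genome
## and noise-free CTSS recovery is exact.
fix_upstream_base <- function(genome, chrom, tss, strand) {
  pos <- if (strand == "+") tss - 1L else tss + 1L
  if (pos >= 0L && pos < nchar(genome[[chrom]]))
    genome <- plant_sequence(genome, chrom, pos, "T")
  genome
}

## One planted transcript: exon widths in transcript order + intron
## widths; returns genomic exon matrix anchored at the TSS.
layout_exons <- function(tss, strand, exon_w, intron_w) {
  stopifnot(length(intron_w) == length(exon_w) - 1L)
  if (strand == "+") {
    starts <- tss + cumsum(c(0L, exon_w[-length(exon_w)] + intron_w))
    exon_matrix(starts, starts + exon_w)
  } else {
    ends <- tss + 1L - cumsum(c(0L, exon_w[-length(exon_w)] + intron_w))
    exon_matrix(ends - exon_w, ends)
  }
}

#' Generate the toy reference: genome, annotation, TE catalog, truth
#'
#' Builds a deterministic synthetic data set. Annotated genes are
#' planted as multi-exon transcripts with an A-free 5' UTR, a random
#' coding sequence (verified to be the transcript's longest ORF), and a
#' stop codon inside the last exon (NMD-safe). Cryptic promoters are
#' planted inside young TE elements, at least 200 bp from any
#' same-strand annotated TSS and away from annotated exons; the first
#' cryptic unit is an LTR12C inside a proviral HERV interval and is
#' expressed only in the treated condition (the drug-induced unit), the
#' second sits in a host gene's first intron (genic context, expressed
#' in both conditions), and the rest are intergenic. One segment is
#' copied verbatim to another locus so its interior k-mers are
#' non-unique.
#'
#' @param spec A [toy_genome_spec()].
#' @param config A [pipeline_config()] (TSO layout and cap-G rate are
#'   shared with the simulator and the trimmer).
#' @return A list with elements `genome` (named character vector),
#'   `annotation` (transcript model table of annotated genes only),
#'   `te_catalog` (data.table), and `truth` (class `lrcage_truth`)
#'   carrying all planted ground truth: transcript models (annotated +
#'   cryptic), true TSSs, TE promoters, per-condition expression,
#'   reference proteome, planted peptides, and duplicated segments.
#' @export
make_toy_reference <- function(spec, config = pipeline_config()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  with_seed(spec$seed, make_toy_reference_impl(spec, config))
}

make_toy_reference_impl <- function(spec, config) {
  chroms <- sprintf("chrT%d", seq_len(spec$n_chroms))
  genome <- setNames(
    vapply(chroms, function(x) random_dna(spec$chrom_length), character(1)),
    chroms)

  gap <- 600L
  cursor <- setNames(rep(1000L, spec$n_chroms), chroms)
  reserve <- function(width, prefer) {
    order_try <- c(prefer, setdiff(seq_len(spec$n_chroms), prefer))
    for (ci in order_try) {
      ch <- chroms[ci]
      if (cursor[[ch]] + width + 1000L <= spec$chrom_length) {
        at <- cursor[[ch]]
        cursor[[ch]] <<- cursor[[ch]] + width + gap
        return(list(chrom = ch, start = at))
      }
    }
    stop("toy genome too small for the requested content", call. = FALSE)
  }

  pal <- te_palette()
  models <- list(); te_rows <- list(); proviral <- list()
  expr <- list(); planted <- list()
  intron_host <- NULL   # exon chain of the gene hosting an intronic TE

  ## ---- annotated genes -------------------------------------------------
  host_gene_idx <- 1L
  for (g in seq_len(spec$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_aa <- sample(140:200, 1L)
    u5 <- 40L; cds_len <- 3L * n_aa + 3L; u3 <- 90L
    tx_len <- u5 + cds_len + u3
    if (g == host_gene_idx) {
      exon_w <- c(250L, tx_len - 250L)
      intron_w <- 1600L
    } else if (g %% 3L == 0L) {
      j1 <- u5 + 120L; j2 <- u5 + cds_len - 250L
      exon_w <- c(j1, j2 - j1, tx_len - j2)
      intron_w <- sample(150:300, 2L, replace = TRUE)
    } else {
      j1 <- u5 + sample(100:200, 1L)
      exon_w <- c(j1, tx_len - j1)
      intron_w <- sample(150:300, 1L)
    }
    loc <- reserve(sum(exon_w) + sum(intron_w), prefer = (g %% spec$n_chroms) + 1L)
    tss <- if (strand == "+") loc$start else loc$start + sum(exon_w) + sum(intron_w) - 1L
    exons <- layout_exons(tss, strand, exon_w, intron_w)

    tx_seq <- NULL
    for (try in 1:25) {
      cand <- paste0(random_utr5(u5), random_cds(n_aa), random_dna(u3))
      orf <- find_longest_orf(cand, min_aa = 50L)
      if (!is.null(orf) && orf$start == u5 && orf$end == u5 + cds_len) {
        tx_seq <- cand; break
      }
    }
    assert_that(!is.null(tx_seq), "failed to plant a clean CDS")
    genome <- plant_transcript(genome, loc$chrom, exons, strand, tx_seq)
    genome <- fix_upstream_base(genome, loc$chrom, tss, strand)

    cds_blocks <- tx_to_genome_blocks(exons, strand, u5, u5 + cds_len)
    models[[length(models) + 1L]] <- list(
      tx_id = sprintf("TOYT%04d", g), gene_id = sprintf("TOYG%04d", g),
      chrom = loc$chrom, strand = strand, exons = exons,
      biotype = "protein_coding",
      cds_start = min(cds_blocks[, 1L]), cds_end = max(cds_blocks[, 2L]),
      source = "gene", te_id = NA_character_,
      tx_seq = tx_seq, orf_start = u5, orf_end = u5 + cds_len,
      w_control = 2L, w_treated = 2L)
    if (g == host_gene_idx) intron_host <- list(chrom = loc$chrom,
                                                strand = strand, exons = exons,
                                                gene = sprintf("TOYG%04d", g))
  }

  ## ---- cryptic TE promoter units --------------------------------------
  n_cr <- spec$n_cryptic_te_promoters
  yg <- pal[pal$young == TRUE]
  for (k in seq_len(n_cr)) {
    role <- if (k == 1L) "proviral" else if (k == 2L) "intronic" else "intergenic"
    sub <- yg[((k - 1L) %% nrow(yg)) + 1L]
    if (role == "proviral") sub <- yg[which(yg$subfamily == "LTR12C")[1L]]
    if (role == "intronic") sub <- yg[which(yg$subfamily == "LTR12E")[1L]]
    te_len <- 700L
    if (role == "intronic") {
      strand <- intron_host$strand
      ex <- intron_host$exons
      ## first intron in transcript orientation
      intr <- if (strand == "+") c(ex[1L, 2L], ex[2L, 1L])
              else c(ex[nrow(ex) - 1L, 2L], ex[nrow(ex), 1L])
      te_start <- if (strand == "+") intr[1L] + 150L else intr[2L] - 150L - te_len
      chrom <- intron_host$chrom
    } else {
      loc <- reserve(1800L, prefer = ((k + spec$n_genes) %% spec$n_chroms) + 1L)
      chrom <- loc$chrom
      strand <- if (k %% 2L == 1L) "+" else "-"
      te_start <- if (strand == "+") loc$start else loc$start + 1800L - te_len
    }
    te_end <- te_start + te_len
    tss <- if (strand == "+") te_start + 120L else te_end - 121L
    exon_w <- c(250L, 420L); intron_w <- 200L
    exons <- layout_exons(tss, strand, exon_w, intron_w)

    u5 <- 25L
    n_aa <- sample(150:190, 1L)
    cds_len <- 3L * n_aa + 3L
    u3 <- sum(exon_w) - u5 - cds_len
    assert_that(u3 >= 20L, "cryptic transcript layout leaves no 3' UTR")
    tx_seq <- NULL
    for (try in 1:25) {
      cand <- paste0(random_utr5(u5), random_cds(n_aa), random_dna(u3))
      orf <- find_longest_orf(cand, min_aa = 50L)
      if (!is.null(orf) && orf$start == u5 && orf$end == u5 + cds_len) {
        tx_seq <- cand; break
      }
    }
    assert_that(!is.null(tx_seq), "failed to plant a clean cryptic CDS")
    genome <- plant_transcript(genome, chrom, exons, strand, tx_seq)
    genome <- fix_upstream_base(genome, chrom, tss, strand)

    te_id <- sprintf("TE_CR%02d", k)
    te_rows[[length(te_rows) + 1L]] <- data.table(
      te_id = te_id, chrom = chrom, start = te_start, end = te_end,
      strand = strand, subfamily = sub$subfamily, family = sub$family,
      class_name = sub$class_name,
      substitutions = sample(5:30, 1L), insertions = sample(0:10, 1L),
      cryptic = TRUE)
    if (role == "proviral") {
      pv_start <- if (strand == "+") te_start else te_end - 1600L
      proviral[[length(proviral) + 1L]] <- data.table(
        locus_id = sprintf("HERV9_%02d", k), chrom = chrom,
        start = max(0L, pv_start), end = max(0L, pv_start) + 1600L,
        strand = strand, clade = "HERV9")
    }

    cds_blocks <- tx_to_genome_blocks(exons, strand, u5, u5 + cds_len)
    w_ctl <- if (role == "intronic") 1L else 0L
    models[[length(models) + 1L]] <- list(
      tx_id = sprintf("CRYPT%04d", k), gene_id = sprintf("NOVELG%04d", k),
      chrom = chrom, strand = strand, exons = exons,
      biotype = "protein_coding",
      cds_start = min(cds_blocks[, 1L]), cds_end = max(cds_blocks[, 2L]),
      source = "cryptic", te_id = te_id,
      tx_seq = tx_seq, orf_start = u5, orf_end = u5 + cds_len,
      w_control = w_ctl, w_treated = 3L)
  }

  ## ---- background TE elements -----------------------------------------
  n_bg <- spec$n_te_elements - n_cr
  for (b in seq_len(max(0L, n_bg)) ) {
    sub <- pal[((b - 1L) %% nrow(pal)) + 1L]
    len <- sample(400:1200, 1L)
    loc <- reserve(len, prefer = (b %% spec$n_chroms) + 1L)
    strand <- sample(c("+", "-"), 1L)
    subs <- if (sub$young) sample(3:40, 1L) else sample(80:300, 1L)
    te_rows[[length(te_rows) + 1L]] <- data.table(
      te_id = sprintf("TE_BG%03d", b), chrom = loc$chrom, start = loc$start,
      end = loc$start + len, strand = strand, subfamily = sub$subfamily,
      family = sub$family, class_name = sub$class_name,
      substitutions = subs, insertions = sample(0:20, 1L), cryptic = FALSE)
  }

  ## ---- duplicated (low-mappability) segment ---------------------------
  dl <- spec$duplicated_segment_length
  src <- reserve(dl, prefer = 1L)
  dst <- reserve(dl, prefer = spec$n_chroms)
  seg <- substr(genome[[src$chrom]], src$start + 1L, src$start + dl)
  genome <- plant_sequence(genome, dst$chrom, dst$start, seg)
  dup_segments <- data.table(
    chrom = c(src$chrom, dst$chrom), start = c(src$start, dst$start),
    end = c(src$start + dl, dst$start + dl), role = c("source", "copy"))

  ## ---- assemble tables -------------------------------------------------
  mdt <- rbindlist(lapply(models, function(m) {
    data.table(tx_id = m$tx_id, gene_id = m$gene_id, chrom = m$chrom,
               strand = m$strand, biotype = m$biotype,
               cds_start = m$cds_start, cds_end = m$cds_end,
               source = m$source, te_id = m$te_id, tx_seq = m$tx_seq,
               orf_start = m$orf_start, orf_end = m$orf_end,
               w_control = m$w_control, w_treated = m$w_treated)
  }))
  mdt[, exons := lapply(models, `[[`, "exons")]
  mdt[, tss := vapply(seq_len(.N), function(i) tss_of(exons[[i]], strand[i]),
                      integer(1))]
  mdt[, tx_length := vapply(exons, function(e) sum(exon_widths(e)), integer(1))]

  te_catalog <- if (length(te_rows)) rbindlist(te_rows) else
    data.table(te_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), subfamily = character(),
               family = character(), class_name = character(),
               substitutions = integer(), insertions = integer(),
               cryptic = logical())
  proviral <- if (length(proviral)) rbindlist(proviral) else
    data.table(locus_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), clade = character())

  expr <- mdt[, .(tx_id, w_control, w_treated)]
  expr[, tpm_control := if (sum(w_control) > 0) w_control / sum(w_control) * 1e6 else 0]
  expr[, tpm_treated := if (sum(w_treated) > 0) w_treated / sum(w_treated) * 1e6 else 0]

  ref_proteome <- mdt[source == "gene",
                      .(protein_id = paste0(gene_id, "_P1"), gene_id,
                        sequence = vapply(seq_len(.N), function(i)
                          translate_dna(substr(tx_seq[i], orf_start[i] + 1L,
                                               orf_end[i] - 3L)),
                          character(1)))]

  planted <- plant_peptides(mdt, ref_proteome)

  true_tss <- mdt[, .(chrom, pos = tss, strand, tx_id, type = source)]
  true_te_promoters <- mdt[source == "cryptic",
                           .(te_id, tx_id, chrom, pos = tss, strand)]

  ann_idx <- mdt$source == "gene"
  annotation <- transcript_models(
    tx_id = mdt$tx_id[ann_idx], gene_id = mdt$gene_id[ann_idx],
    chrom = mdt$chrom[ann_idx], strand = mdt$strand[ann_idx],
    exons = mdt$exons[ann_idx], biotype = mdt$biotype[ann_idx],
    cds_start = mdt$cds_start[ann_idx], cds_end = mdt$cds_end[ann_idx])

  truth <- structure(list(
    spec = spec, genome = genome, models = mdt, annotation = annotation,
    te_catalog = te_catalog, proviral = proviral, true_tss = true_tss,
    true_te_promoters = true_te_promoters, expression = expr,
    ref_proteome = ref_proteome, planted_peptides = planted,
    duplicated_segments = dup_segments,
    tso = list(linker = config$tso_linker, umi_length = config$umi_length,
               spacer = config$tso_spacer),
    cap_g_rate = config$cap_g_rate), class = "lrcage_truth")

  list(genome = genome, annotation = annotation, te_catalog = te_catalog,
       truth = truth)
}

## Peptides planted for the antigen stage:
##  P1 canonical     - copied from an annotated protein, detected in both
##  P2 noncanonical  - TE-coded 9-mer of the drug-induced cryptic unit,
##                     detected under treatment only
##  P3 noncanonical  - non-TE-coded 9-mer of the constitutive (intronic)
##                     cryptic unit, detected in both conditions
plant_peptides <- function(mdt, ref_proteome) {
  out <- list()
  if (nrow(ref_proteome)) {
    p1 <- substr(ref_proteome$sequence[min(2L, nrow(ref_proteome))], 30L, 38L)
    out[[1L]] <- data.table(peptide_id = "PEP_CANON", sequence = p1,
                            tx_id = NA_character_,
                            detected_control = TRUE, detected_treated = TRUE,
                            expected_class = "canonical")
  }
  crypt <- mdt[source == "cryptic"]
  pick_unique <- function(protein, from, to, width = 9L) {
    for (s in seq(from, to)) {
      pep <- substr(protein, s, s + width - 1L)
      if (nchar(pep) < width) next
      if (!any(vapply(ref_proteome$sequence, function(r)
        grepl(pep, r, fixed = TRUE), logical(1)))) return(pep)
    }
    NULL
  }
  if (nrow(crypt) >= 1L) {
    m <- crypt[1L]
    prot <- translate_dna(substr(m$tx_seq, m$orf_start + 1L, m$orf_end - 3L))
    pep <- pick_unique(prot, 20L, 40L)   # aa 20..: TE-coded (first exon)
    if (!is.null(pep))
      out[[length(out) + 1L]] <- data.table(
        peptide_id = "PEP_TE_INDUCED", sequence = pep, tx_id = m$tx_id,
        detected_control = FALSE, detected_treated = TRUE,
        expected_class = "noncanonical_te")
  }
  if (nrow(crypt) >= 2L) {
    m <- crypt[2L]
    prot <- translate_dna(substr(m$tx_seq, m$orf_start + 1L, m$orf_end - 3L))
    pep <- pick_unique(prot, 131L, nchar(prot) - 9L)  # 3'-exon, non-TE codons
    if (!is.null(pep))
      out[[length(out) + 1L]] <- data.table(
        peptide_id = "PEP_NONTE", sequence = pep, tx_id = m$tx_id,
        detected_control = TRUE, detected_treated = TRUE,
        expected_class = "noncanonical_non_te")
  }
  if (length(out)) rbindlist(out) else
    data.table(peptide_id = character(), sequence = character(),
               tx_id = character(), detected_control = logical(),
               detected_treated = logical(), expected_class = character())
}

#' @export
print.lrcage_truth <- function(x, ...) {
  cat(sprintf(
    "lrcage toy truth: %d chroms, %d transcripts (%d cryptic), %d TEs\n",
    x$spec$n_chroms, nrow(x$models), sum(x$models$source == "cryptic"),
    nrow(x$te_catalog)))
  invisible(x)
}

encode_umi <- function(idx0, width = 8L) {
  letters4 <- c("A", "C", "G", "T")
  vapply(idx0, function(v) {
    d <- integer(width)
    for (p in seq_len(width)) { d[p] <- v %% 4L; v <- v %/% 4L }
    paste(letters4[d + 1L], collapse = "")
  }, character(1))
}

#' Simulate CAGE reads from the toy truth
#'
#' Emits raw reads (TSO linker + UMI + spacer prefix, an unencoded cap G
#' on most capped molecules, and a 15-A tail for LRCAGE), their
#' alignments (as produced by an aligner on the trimmed reads: the cap G
#' and any artifact bases appear as 5' soft-clips), and a per-read truth
#' table. Protocols: `LRCAGE` spans TSS to poly(A); `LRhex` spans TSS to
#' a random internal point at least 250 nt downstream; `nanoCAGE` is a
#' short 75-nt 5' fragment. A `noise` fraction of molecules receives one
#' artifact: a PCR `duplicate` (extra copy, same UMI and coordinates),
#' `excess_clip` (four extra 5' soft-clipped bases), or `truncated`
#' (recapping artifact: 5' end 30-60 nt downstream of the TSS, no cap
#' G).
#'
#' @param truth An `lrcage_truth` from [make_toy_reference()].
#' @param protocol One of `"LRCAGE"`, `"LRhex"`, `"nanoCAGE"`.
#' @param depth Reads per unit of expression weight (>= 1).
#' @param noise Fraction of molecules given an artifact.
#' @param condition `"treated"` or `"control"`; selects the expression
#'   weights used to decide how many molecules each transcript emits.
#' @param seed Optional integer; defaults to a value derived from the
#'   spec seed, protocol, and condition.
#' @return A list: `reads` (data.table read_id/sequence), `alignments`
#'   (alignment table, see [filter_alignment()]), `read_truth`
#'   (read_id, tx_id, molecule, artifact, capped, has_g).
#' @export
simulate_cage_reads <- function(truth, protocol = c("LRCAGE", "LRhex", "nanoCAGE"),
                                depth = 3L, noise = 0,
                                condition = c("treated", "control"),
                                seed = NULL) {
  stopifnot(inherits(truth, "lrcage_truth"))
  protocol <- match.arg(protocol)
  condition <- match.arg(condition)
  assert_count(depth, "depth")
  assert_that(is.numeric(noise) && noise >= 0 && noise <= 1,
              "'noise' must lie in [0, 1]")
  if (is.null(seed))
    seed <- truth$spec$seed * 13L + 7L * (condition == "treated") +
      match(protocol, c("LRCAGE", "LRhex", "nanoCAGE"))
  with_seed(seed, simulate_cage_reads_impl(truth, protocol, depth, noise,
                                           condition))
}

simulate_cage_reads_impl <- function(truth, protocol, depth, noise, condition) {
  mdt <- truth$models
  wcol <- if (condition == "treated") "w_treated" else "w_control"
  linker <- truth$tso$linker; spacer <- truth$tso$spacer
  umi_w <- truth$tso$umi_length
  reads <- list(); alns <- list(); rtruth <- list()

  for (i in seq_len(nrow(mdt))) {
    w <- mdt[[wcol]][i]
    n_mol <- depth * w
    if (n_mol == 0L) next
    tx_seq <- mdt$tx_seq[i]; txlen <- nchar(tx_seq)
    exons <- mdt$exons[[i]]; strand <- mdt$strand[i]; chrom <- mdt$chrom[i]
    umis <- encode_umi(sample.int(4L^umi_w, n_mol) - 1L, umi_w)
    for (m in seq_len(n_mol)) {
      artifact <- "none"
      if (noise > 0 && runif(1) < noise)
        artifact <- sample(c("duplicate", "excess_clip", "truncated"), 1L)
      capped <- artifact != "truncated"
      has_g <- capped && runif(1) < truth$cap_g_rate
      start_off <- if (artifact == "truncated") sample(30:60, 1L) else 0L
      end_off <- switch(protocol,
        LRCAGE = txlen,
        LRhex = sample(seq(min(start_off + 250L, txlen), txlen), 1L),
        nanoCAGE = min(start_off + 75L, txlen))
      insert <- substr(tx_seq, start_off + 1L, end_off)
      extra5 <- if (artifact == "excess_clip") random_dna(4L) else ""
      clip5_seq <- paste0(extra5, if (has_g) "G" else "")
      raw <- paste0(linker, umis[m], spacer, clip5_seq, insert,
                    if (protocol == "LRCAGE") strrep("A", 15L) else "")
      blocks <- tx_to_genome_blocks(exons, strand, start_off, end_off)
      n_copies <- if (artifact == "duplicate") 2L else 1L
      for (cp in seq_len(n_copies)) {
        rid <- sprintf("%s_%s_%s_m%04d_r%d", protocol, condition,
                       mdt$tx_id[i], m, cp)
        reads[[length(reads) + 1L]] <- data.table(read_id = rid, sequence = raw)
        alns[[length(alns) + 1L]] <- data.table(
          read_id = rid, chrom = chrom, strand = strand,
          clip5 = nchar(clip5_seq), clip3 = 0L,
          clip5_seq = clip5_seq, clip3_seq = "",
          umi = umis[m], mapq = 60L, is_primary = TRUE,
          is_supplementary = FALSE, is_unique = TRUE,
          seq = paste0(clip5_seq, insert))
        alns[[length(alns)]]$blocks <- list(blocks)
        rtruth[[length(rtruth) + 1L]] <- data.table(
          read_id = rid, tx_id = mdt$tx_id[i], molecule = m,
          artifact = artifact, capped = capped, has_g = has_g,
          condition = condition, protocol = protocol)
      }
    }
  }
  list(reads = if (length(reads)) rbindlist(reads) else
         data.table(read_id = character(), sequence = character()),
       alignments = if (length(alns)) rbindlist(alns) else
         empty_alignments(),
       read_truth = if (length(rtruth)) rbindlist(rtruth) else
         data.table(read_id = character(), tx_id = character(),
                    molecule = integer(), artifact = character(),
                    capped = logical(), has_g = logical(),
                    condition = character(), protocol = character()))
}

empty_alignments <- function() {
  data.table(read_id = character(), chrom = character(), strand = character(),
             clip5 = integer(), clip3 = integer(), clip5_seq = character(),
             clip3_seq = character(), umi = character(), mapq = integer(),
             is_primary = logical(), is_supplementary = logical(),
             is_unique = logical(), seq = character(), blocks = list())
}
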