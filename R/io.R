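#' Write a genome as FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome_as_character(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a genome FASTA into the internal representation
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  genome_as_character(x)
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.table with `read_id`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      strrep("I", nchar(reads$sequence))), con)
  invisible(path)
}

#' Read FASTQ into the simulator's read table
#' @param path FASTQ file.
#' @return data.table with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x))
}

blocks_to_cigar <- function(blocks, clip5, clip3, strand) {
  ## CIGAR is reported in reference orientation; for minus-strand reads
  ## the 5' clip of the read is the right-hand (3'-coordinate) clip.
  widths <- blocks[, 2L] - blocks[, 1L]
  gaps <- if (nrow(blocks) > 1L) blocks[-1L, 1L] - blocks[-nrow(blocks), 2L]
    else integer(0)
  body <- paste0(widths[1L], "M")
  for (i in seq_along(gaps))
    body <- paste0(body, gaps[i], "N", widths[i + 1L], "M")
  left <- if (strand == "+") clip5 else clip3
  right <- if (strand == "+") clip3 else clip5
  paste0(if (left > 0L) paste0(left, "S") else "", body,
         if (right > 0L) paste0(right, "S") else "")
}

#' Write an alignment table as SAM
#'
#' Emits a valid header (`@SQ` lines from the genome) and one record
#' per alignment with soft-clip aware CIGARs, `RX` (UMI) and `NH` tags.
#' Sequences are written in reference orientation, as an aligner would.
#'
#' @param alignments Alignment table (see [filter_alignment()]).
#' @param genome Named character vector or `DNAStringSet` (for `@SQ`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  seqs <- genome_as_character(genome)
  aln <- as.data.table(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)), con)
  for (i in seq_len(nrow(aln))) {
    blocks <- aln$blocks[[i]]
    flag <- 0L
    if (aln$strand[i] == "-") flag <- flag + 16L
    if (!aln$is_primary[i]) flag <- flag + 256L
    if (aln$is_supplementary[i]) flag <- flag + 2048L
    seq_out <- aln$seq[i] %||% "*"
    if (!is.na(seq_out) && seq_out != "*" && aln$strand[i] == "-")
      seq_out <- revcomp(seq_out)
    writeLines(paste(
      aln$read_id[i], flag, aln$chrom[i], blocks[1L, 1L] + 1L,
      aln$mapq[i],
      blocks_to_cigar(blocks, aln$clip5[i], aln$clip3[i], aln$strand[i]),
      "*", 0L, 0L, seq_out, "*",
      paste0("RX:Z:", aln$umi[i]),
      paste0("NH:i:", if (aln$is_unique[i]) 1L else 2L),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM/BAM file into the alignment table
#'
#' Uses `Rsamtools`/`GenomicAlignments`: SAM input is converted to BAM
#' first. Soft-clip lengths and aligned blocks are derived from the
#' CIGAR; the UMI is taken from the `RX` tag and uniqueness from `NH`.
#' The 5'/3' clip orientation is read-strand-relative.
#'
#' @param path SAM or BAM file.
#' @return Alignment table (see [filter_alignment()]).
#' @export
read_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(
    tag = c("RX", "NH"),
    what = c("seq", "mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, use.names = TRUE,
                                           param = param)
  n <- length(ga)
  if (n == 0L) return(empty_alignments())
  cig <- GenomicAlignments::cigar(ga)
  strand <- as.character(GenomicAlignments::strand(ga))
  blocks_gr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = "M", pos = GenomicAlignments::start(ga), reduce.ranges = TRUE)
  left_clip <- integer(length(cig))
  has_l <- grepl("^[0-9]+S", cig)
  left_clip[has_l] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cig[has_l]))
  right_clip <- integer(length(cig))
  has_r <- grepl("[0-9]+S$", cig)
  right_clip[has_r] <- as.integer(sub("^.*?([0-9]+)S$", "\\1", cig[has_r]))
  clip5 <- ifelse(strand == "+", left_clip, right_clip)
  clip3 <- ifelse(strand == "+", right_clip, left_clip)
  flags <- S4Vectors::mcols(ga)$flag
  seq_ref <- as.character(S4Vectors::mcols(ga)$seq)
  seq_read <- ifelse(strand == "-" & !is.na(seq_ref) & nzchar(seq_ref),
                     revcomp(seq_ref), seq_ref)
  clip5_seq <- substr(seq_read, 1L, clip5)
  clip3_seq <- substr(seq_read, nchar(seq_read) - clip3 + 1L,
                      nchar(seq_read))
  nh <- S4Vectors::mcols(ga)$NH
  out <- data.table(
    read_id = names(ga),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = strand,
    clip5 = clip5, clip3 = clip3,
    clip5_seq = clip5_seq, clip3_seq = clip3_seq,
    umi = S4Vectors::mcols(ga)$RX %||% "",
    mapq = S4Vectors::mcols(ga)$mapq,
    is_primary = !bitwAnd(flags, 256L),
    is_supplementary = bitwAnd(flags, 2048L) > 0L,
    is_unique = if (is.null(nh)) NA else nh == 1L,
    seq = seq_read)
  out[, blocks := lapply(seq_len(n), function(i) {
    r <- blocks_gr[[i]]
    exon_matrix(GenomicAlignments::start(r) - 1L, GenomicAlignments::end(r))
  })]
  out[]
}

#' Write / read a TE catalog as extended BED (BED6+5)
#'
#' Columns 1-6 are standard BED (name = `te_id`, score = 0); extra
#' columns carry `subfamily`, `family`, `class_name`, `substitutions`,
#' `insertions`.
#'
#' @param te_catalog TE catalog data.table.
#' @param path File path.
#' @return `write_te_catalog` returns `path` invisibly;
#'   `read_te_catalog` returns the catalog.
#' @export
write_te_catalog <- function(te_catalog, path) {
  te <- as.data.table(te_catalog)
  out <- te[, .(chrom, start, end, te_id, score = 0L, strand, subfamily,
                family, class_name, substitutions, insertions)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_te_catalog
#' @export
read_te_catalog <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "te_id", "score",
                            "strand", "subfamily", "family", "class_name",
                            "substitutions", "insertions"))
  dt[, score := NULL]
  setcolorder(dt, c("te_id", "chrom", "start", "end", "strand", "subfamily",
                    "family", "class_name", "substitutions", "insertions"))
  dt[]
}

#' Write CTSS records as a BED-like TSV
#' @param ctss CTSS table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(ctss, path) {
  fwrite(as.data.table(ctss), path, sep = "\t")
  invisible(path)
}

#' Write peaks as BED6+ with density/cap columns
#' @param peaks Tag cluster table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  fwrite(as.data.table(peaks), path, sep = "\t")
  invisible(path)
}

#' Export a complete fixture to a directory
#'
#' Writes the toy genome (FASTA), annotation (GTF), TE catalog (BED6+),
#' proviral loci, expression, true TSSs, and planted peptides (TSV).
#'
#' @param reference Output of [make_toy_reference()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- reference$truth
  write_genome_fasta(reference$genome, file.path(dir, "genome.fa"))
  write_models_gtf(reference$annotation, file.path(dir, "annotation.gtf"))
  write_te_catalog(reference$te_catalog, file.path(dir, "te_catalog.bed"))
  fwrite(truth$proviral, file.path(dir, "proviral.tsv"), sep = "\t")
  fwrite(truth$expression, file.path(dir, "expression.tsv"), sep = "\t")
  fwrite(truth$true_tss, file.path(dir, "true_tss.tsv"), sep = "\t")
  fwrite(truth$planted_peptides, file.path(dir, "peptides.tsv"), sep = "\t")
  invisible(dir)
}
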