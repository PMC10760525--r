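## Translate a DNA string (first frame, truncated to whole codons).
## Stops appear as '*'.
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n)),
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

#' Find the longest ORF in a transcript sequence
#'
#' Scans the three forward frames for ATG-initiated, stop-terminated
#' open reading frames and returns the longest with at least `min_aa`
#' residues; ties are broken toward the 5'-most start. ORFs running off
#' the 3' end (no in-transcript stop codon) are excluded.
#'
#' @param seq Transcript sequence over `{A,C,G,T,N}` (5' to 3').
#' @param min_aa Minimum protein length in amino acids (default 100).
#' @return `NULL`, or a list with `start`/`end` (transcript
#'   coordinates, 0-based half-open, including the stop codon),
#'   `protein` (no stop), `frame` (0-2), `n_aa`.
#' @export
find_longest_orf <- function(seq, min_aa = 100L) {
  assert_that(is.character(seq) && length(seq) == 1L && nzchar(seq),
              "sequence must be a nonempty string")
  best <- NULL
  for (f in 0:2) {
    prot <- translate_dna(substr(seq, f + 1L, nchar(seq)))
    if (!nzchar(prot)) next
    m_pos <- which(strsplit(prot, "")[[1]] == "M")
    if (!length(m_pos)) next
    stop_pos <- which(strsplit(prot, "")[[1]] == "*")
    if (!length(stop_pos)) next
    ## for each M, the first stop at or after it
    nxt <- stop_pos[findInterval(m_pos - 1L, stop_pos) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len_aa <- nxt[ok] - m_pos[ok]          # residues before the stop
    for (idx in seq_along(len_aa)) {
      if (len_aa[idx] < min_aa) next
      cand_start <- f + 3L * (m_pos[ok][idx] - 1L)
      better <- is.null(best) || len_aa[idx] > best$n_aa ||
        (len_aa[idx] == best$n_aa && cand_start < best$start)
      if (better)
        best <- list(start = cand_start,
                     end = cand_start + 3L * (len_aa[idx] + 1L),
                     protein = substr(prot, m_pos[ok][idx],
                                      m_pos[ok][idx] + len_aa[idx] - 1L),
                     frame = f, n_aa = len_aa[idx])
    }
  }
  best
}

#' Nonsense-mediated-decay filter for a predicted ORF
#'
#' Applies the canonical 50-nt rule: the ORF is dropped when its stop
#' codon starts more than `rule_nt` nucleotides upstream of the last
#' exon-exon junction in transcript coordinates. Mono-exonic
#' transcripts are always kept.
#'
#' @param exons Exon matrix of the transcript (genomic, sorted).
#' @param strand Transcript strand.
#' @param orf An ORF list from [find_longest_orf()].
#' @param rule_nt NMD distance threshold (default 50).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
nmd_filter <- function(exons, strand, orf, rule_nt = 50L) {
  stopifnot(is.list(orf), !is.null(orf$end))
  tx_len <- sum(exon_widths(exons))
  assert_that(orf$end <= tx_len && orf$start >= 0L,
              "ORF lies outside the transcript")
  if (nrow(exons) == 1L) return(TRUE)
  w <- exon_widths(exons)
  w_tx_order <- if (strand == "+") w else rev(w)
  last_junction <- tx_len - w_tx_order[length(w_tx_order)]
  stop_start <- orf$end - 3L
  (last_junction - stop_start) <= rule_nt
}

#' Three-frame translation into stop-free peptides
#'
#' Translates all three forward frames, splits at stop codons, and
#' keeps stretches of at least `min_aa` residues. No start codon is
#' required; this is the expanded search used for proviral HERV
#' transcripts whose ORFs are often start-truncated.
#'
#' @param seq Transcript sequence.
#' @param min_aa Minimum peptide length (default 25).
#' @return data.table: `frame` (0-2), `start_aa` (0-based offset in the
#'   frame translation), `peptide`.
#' @export
three_frame_peptides <- function(seq, min_aa = 25L) {
  assert_that(is.character(seq) && length(seq) == 1L && nzchar(seq),
              "sequence must be a nonempty string")
  out <- list()
  for (f in 0:2) {
    prot <- translate_dna(substr(seq, f + 1L, nchar(seq)))
    if (!nzchar(prot)) next
    pieces <- strsplit(prot, "*", fixed = TRUE)[[1]]
    if (!length(pieces)) next
    offs <- cumsum(c(0L, nchar(pieces) + 1L))[seq_along(pieces)]
    keep <- nchar(pieces) >= min_aa
    if (any(keep))
      out[[length(out) + 1L]] <- data.table(frame = f,
                                            start_aa = offs[keep],
                                            peptide = pieces[keep])
  }
  if (length(out)) rbindlist(out) else
    data.table(frame = integer(), start_aa = integer(),
               peptide = character())
}

#' Amino-acid ranges of an ORF encoded by TE-overlapping sequence
#'
#' Intersects the transcript's exons with TE elements, maps the
#' overlap into transcript coordinates, and marks every residue whose
#' codon overlaps TE-derived sequence.
#'
#' @param exons,strand,chrom Transcript location.
#' @param orf ORF list from [find_longest_orf()].
#' @param te_catalog TE catalog.
#' @return Integer matrix with columns `start`, `end`: 1-based closed
#'   residue ranges (possibly zero rows).
#' @export
te_coded_ranges <- function(exons, strand, chrom, orf, te_catalog) {
  te <- as.data.table(te_catalog)
  n_aa <- (orf$end - orf$start) %/% 3L - 1L
  if (nrow(te) == 0L || n_aa < 1L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  te <- te[te$chrom == chrom & te$end > exons[1L, 1L] &
             te$start < exons[nrow(exons), 2L]]
  if (nrow(te) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  ## transcript-coordinate offsets of each exon, in transcript order
  w <- exon_widths(exons)
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  offs <- cumsum(c(0L, w[ord]))[seq_along(ord)]
  te_nt <- logical(sum(w))
  for (i in seq_along(ord)) {
    e <- ord[i]
    for (r in seq_len(nrow(te))) {
      lo <- max(exons[e, 1L], te$start[r]); hi <- min(exons[e, 2L], te$end[r])
      if (lo >= hi) next
      if (strand == "+") {
        a <- offs[i] + (lo - exons[e, 1L]); b <- offs[i] + (hi - exons[e, 1L])
      } else {
        a <- offs[i] + (exons[e, 2L] - hi); b <- offs[i] + (exons[e, 2L] - lo)
      }
      te_nt[(a + 1L):b] <- TRUE
    }
  }
  aa_hit <- vapply(seq_len(n_aa), function(i) {
    cod <- orf$start + 3L * (i - 1L) + 1:3
    any(te_nt[cod])
  }, logical(1))
  if (!any(aa_hit))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  r <- rle(aa_hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

## Longest prefix/suffix of `p` occurring anywhere in `r` (fixed
## strings); binary search over lengths.
longest_end_match <- function(p, r, from_start = TRUE) {
  lo <- 0L; hi <- nchar(p)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    piece <- if (from_start) substr(p, 1L, mid)
      else substr(p, nchar(p) - mid + 1L, nchar(p))
    if (grepl(piece, r, fixed = TRUE)) lo <- mid else hi <- mid - 1L
  }
  lo
}

has_shared_block <- function(p, r, min_block) {
  if (nchar(p) < min_block) return(FALSE)
  for (s in seq_len(nchar(p) - min_block + 1L))
    if (grepl(substr(p, s, s + min_block - 1L), r, fixed = TRUE))
      return(TRUE)
  FALSE
}

#' Classify a predicted protein against the reference proteome
#'
#' Classes, in decision order:
#' * `annotated` - exact match to any reference protein;
#' * `truncated` - proper substring of a same-gene reference protein;
#' * `chimeric` - contains a full same-gene reference protein plus
#'   novel flanking sequence;
#' * `novel_internal` - both a prefix and a suffix (each at least
#'   `min_block` aa) match a same-gene reference, with novel internal
#'   sequence;
#' * `chimeric_truncated` - a terminal block of at least `min_block` aa
#'   matches a same-gene reference with novel sequence on the other
#'   side (also the fallback when only an internal block is shared);
#' * `out_of_frame` / `unannotated_coding` - no shared block of
#'   `min_block` aa with any same-gene reference; `out_of_frame` when
#'   the transcript overlaps an annotated CDS, `unannotated_coding`
#'   otherwise.
#'
#' @param protein Amino-acid string.
#' @param ref_proteome data.table: `protein_id`, `gene_id`, `sequence`.
#' @param gene_id Gene context of the encoding transcript (`NA` for
#'   novel genes).
#' @param overlaps_cds Does the encoding transcript overlap an
#'   annotated CDS?
#' @param min_block Minimum shared block in aa (default 10).
#' @return Character class label.
#' @export
classify_protein <- function(protein, ref_proteome, gene_id = NA,
                             overlaps_cds = FALSE, min_block = 10L) {
  ref <- as.data.table(ref_proteome)
  if (nrow(ref) && protein %in% ref$sequence) return("annotated")
  same <- if (is.na(gene_id)) ref[0L] else ref[ref$gene_id == gene_id]
  fallback <- if (isTRUE(overlaps_cds)) "out_of_frame" else "unannotated_coding"
  if (nrow(same) == 0L) return(fallback)
  verdicts <- vapply(same$sequence, function(r) {
    if (grepl(protein, r, fixed = TRUE)) return("truncated")
    if (grepl(r, protein, fixed = TRUE)) return("chimeric")
    pre <- longest_end_match(protein, r, from_start = TRUE)
    suf <- longest_end_match(protein, r, from_start = FALSE)
    if (pre >= min_block && suf >= min_block &&
        pre + suf < nchar(protein)) return("novel_internal")
    if (pre >= min_block || suf >= min_block) return("chimeric_truncated")
    if (has_shared_block(protein, r, min_block)) return("chimeric_truncated")
    "none"
  }, character(1))
  rank <- c(truncated = 1L, chimeric = 2L, novel_internal = 3L,
            chimeric_truncated = 4L, none = 5L)
  best <- verdicts[which.min(rank[verdicts])]
  if (best == "none") fallback else unname(best)
}

#' Build the merged custom proteome
#'
#' Unions the reference proteome with novel predicted proteins,
#' dropping novel entries whose sequence exactly duplicates a reference
#' protein. Novel proteins are named `<gene_or_transcript>_NP_<n>` with
#' deterministic per-gene numbering, so output order is stable.
#'
#' @param novel data.table: `sequence`, `gene_id` (or novel-gene
#'   label), `tx_id`, `class`, plus optional `te_ranges` (list column
#'   of TE-coded residue ranges).
#' @param ref_proteome data.table: `protein_id`, `gene_id`, `sequence`.
#' @return data.table of class `lrcage_proteome`: `protein_id`,
#'   `gene_id`, `tx_id`, `sequence`, `class`, `source`
#'   (`reference`/`novel`), `te_ranges`.
#' @export
build_custom_proteome <- function(novel, ref_proteome) {
  ref <- as.data.table(ref_proteome)
  nov <- as.data.table(novel)
  empty_ranges <- matrix(integer(0), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  out_ref <- data.table(protein_id = ref$protein_id, gene_id = ref$gene_id,
                        tx_id = NA_character_, sequence = ref$sequence,
                        class = "annotated", source = "reference")
  out_ref[, te_ranges := list(rep(list(empty_ranges), .N))]
  if (nrow(nov)) {
    nov <- nov[!sequence %in% ref$sequence]
  }
  if (nrow(nov)) {
    if (!"te_ranges" %in% names(nov))
      nov[, te_ranges := list(rep(list(empty_ranges), .N))]
    setorder(nov, gene_id, tx_id, sequence)
    nov[, protein_id := paste0(gene_id, "_NP_", seq_len(.N)), by = gene_id]
    out_nov <- nov[, .(protein_id, gene_id, tx_id, sequence, class, source = "novel",
                       te_ranges)]
    out <- rbindlist(list(out_ref, out_nov), use.names = TRUE)
  } else out <- out_ref
  dup <- out[, .N, by = protein_id][N > 1L]
  if (nrow(dup)) {
    seqs <- out[protein_id %in% dup$protein_id,
                uniqueN(sequence), by = protein_id]
    assert_that(all(seqs$V1 == 1L),
                "duplicate protein ids with different sequences")
    out <- out[!duplicated(protein_id)]
  }
  setattr(out, "class", c("lrcage_proteome", class(out)))
  out[]
}

#' Write a proteome table as FASTA
#'
#' Headers carry the protein id plus `class` and source transcript.
#'
#' @param proteome A proteome table ([build_custom_proteome()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  hdr <- sprintf("%s class=%s%s", proteome$protein_id, proteome$class,
                 ifelse(is.na(proteome$tx_id), "",
                        paste0(" tx=", proteome$tx_id)))
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
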