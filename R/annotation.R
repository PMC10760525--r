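#' Transcript model table
#'
#' The package-wide container for exon-chain transcript models is a
#' `data.table` with one row per transcript and columns:
#' `tx_id`, `gene_id`, `chrom`, `strand`, `exons` (list column of
#' two-column integer matrices, 0-based half-open, genomically sorted),
#' `biotype`, and optional genomic CDS bounds `cds_start`/`cds_end`
#' (0-based half-open; `NA` for noncoding). This constructor validates
#' the invariants (sorted, non-overlapping exons) and derives `tss`
#' (genomic position of the 5'-most transcribed base) and `tx_length`.
#'
#' @param tx_id,gene_id,chrom,strand,biotype Character vectors.
#' @param exons List of exon matrices, one per transcript.
#' @param cds_start,cds_end Optional genomic CDS bounds.
#' @return A validated `data.table` of transcript models.
#' @export
transcript_models <- function(tx_id, gene_id, chrom, strand, exons,
                              biotype = "protein_coding",
                              cds_start = NA_integer_, cds_end = NA_integer_) {
  n <- length(tx_id)
  dt <- data.table(
    tx_id = as.character(tx_id), gene_id = as.character(gene_id),
    chrom = as.character(chrom), strand = as.character(strand),
    exons = exons,
    biotype = rep_len(as.character(biotype), n),
    cds_start = rep_len(as.integer(cds_start), n),
    cds_end = rep_len(as.integer(cds_end), n)
  )
  assert_that(all(dt$strand %in% c("+", "-")), "strand must be '+' or '-'")
  for (i in seq_len(n)) {
    ex <- dt$exons[[i]]
    assert_that(is.matrix(ex) && ncol(ex) == 2L && nrow(ex) >= 1L,
                sprintf("transcript %s: exons must be a 2-column matrix",
                        dt$tx_id[i]))
    assert_that(all(ex[, 2L] > ex[, 1L]),
                sprintf("transcript %s: empty exon", dt$tx_id[i]))
    if (nrow(ex) > 1L)
      assert_that(all(ex[-1L, 1L] >= ex[-nrow(ex), 2L]),
                  sprintf("transcript %s: exons unsorted or overlapping",
                          dt$tx_id[i]))
  }
  dt[, tss := vapply(seq_len(.N), function(i) tss_of(exons[[i]], strand[i]),
                     integer(1))]
  dt[, tx_length := vapply(exons, function(e) sum(exon_widths(e)), integer(1))]
  dt[]
}

#' Splice-junction chain of a transcript model
#'
#' Junctions are intron intervals keyed as `"chrom:strand:start-end"`,
#' ordered 5' to 3' in transcript orientation.
#' @keywords internal
junction_chain <- function(chrom, strand, exons) {
  if (nrow(exons) < 2L) return(character(0))
  key <- sprintf("%s:%s:%d-%d", chrom, strand,
                 exons[-nrow(exons), 2L], exons[-1L, 1L])
  if (strand == "-") rev(key) else key
}

#' Index a transcript annotation for interval queries
#'
#' Builds the strand-aware feature index used by peak annotation,
#' cryptic TSS calling, and novelty classification: annotated TSSs,
#' promoter windows, 5'/3' UTRs, first/other exons, introns, and gene
#' bodies.
#'
#' @param models Transcript model table (see [transcript_models()]).
#' @param promoter_upstream,promoter_downstream Strand-aware promoter
#'   window around each annotated TSS, in bp.
#' @return An object of class `lrcage_annotation`.
#' @export
tx_annotation <- function(models, promoter_upstream = 500L,
                          promoter_downstream = 100L) {
  stopifnot(is.data.table(models), nrow(models) >= 1L)
  feat <- list(promoter = list(), utr5 = list(), first_exon = list(),
               utr3 = list(), other_exon = list(), intron = list())
  genes <- list()
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    chrom <- models$chrom[i]; strand <- models$strand[i]
    tss <- models$tss[i]
    if (strand == "+") {
      pr <- c(tss - promoter_upstream, tss + promoter_downstream)
    } else {
      pr <- c(tss - promoter_downstream + 1L, tss + promoter_upstream + 1L)
    }
    add <- function(slot, s, e, str = strand) {
      s <- pmax(s, 0L)
      if (any(e > s))
        feat[[slot]][[length(feat[[slot]]) + 1L]] <<-
          data.table(chrom = chrom, start = s[e > s], end = e[e > s],
                     strand = str)
    }
    add("promoter", pr[1L], pr[2L])
    first_idx <- if (strand == "+") 1L else nrow(ex)
    add("first_exon", ex[first_idx, 1L], ex[first_idx, 2L])
    if (nrow(ex) > 1L)
      add("other_exon", ex[-first_idx, 1L], ex[-first_idx, 2L])
    if (nrow(ex) > 1L)
      add("intron", ex[-nrow(ex), 2L], ex[-1L, 1L])
    if (!is.na(models$cds_start[i])) {
      cs <- models$cds_start[i]; ce <- models$cds_end[i]
      u5 <- if (strand == "+") cbind(ex[, 1L], pmin(ex[, 2L], cs))
            else cbind(pmax(ex[, 1L], ce), ex[, 2L])
      u3 <- if (strand == "+") cbind(pmax(ex[, 1L], ce), ex[, 2L])
            else cbind(ex[, 1L], pmin(ex[, 2L], cs))
      add("utr5", u5[, 1L], u5[, 2L])
      add("utr3", u3[, 1L], u3[, 2L])
    }
    genes[[i]] <- data.table(chrom = chrom, start = ex[1L, 1L],
                             end = ex[nrow(ex), 2L], strand = strand,
                             gene_id = models$gene_id[i])
  }
  feat_dt <- lapply(feat, function(l)
    if (length(l)) rbindlist(l) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character()))
  gene_dt <- rbindlist(genes)[, .(start = min(start), end = max(end)),
                              by = .(gene_id, chrom, strand)]
  tss_dt <- models[, .(chrom, pos = tss, strand, tx_id, gene_id)]
  ref_chains <- lapply(seq_len(nrow(models)), function(i)
    junction_chain(models$chrom[i], models$strand[i], models$exons[[i]]))
  names(ref_chains) <- models$tx_id
  structure(list(models = models, features = feat_dt, genes = gene_dt,
                 tss = tss_dt, ref_chains = ref_chains,
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream)),
            class = "lrcage_annotation")
}

#' @export
print.lrcage_annotation <- function(x, ...) {
  cat(sprintf("lrcage annotation: %d transcripts, %d genes\n",
              nrow(x$models), nrow(x$genes)))
  invisible(x)
}

## points: data.table(chrom, pos, strand); intervals: feature data.table
## Returns logical: point falls in any interval (optionally same strand).
point_in_intervals <- function(points, intervals, stranded = FALSE) {
  if (nrow(intervals) == 0L || nrow(points) == 0L)
    return(rep(FALSE, nrow(points)))
  q <- gr0(points$chrom, points$pos, points$pos + 1L,
           if (stranded) points$strand else "*")
  s <- gr0(intervals$chrom, intervals$start, intervals$end,
           if (stranded) intervals$strand else "*")
  IRanges::overlapsAny(q, s, ignore.strand = !stranded)
}

#' Export transcript models as GTF
#'
#' Writes exon (and CDS, where present) features with `gene_id`,
#' `transcript_id`, and `transcript_biotype` attributes via
#' `rtracklayer`.
#'
#' @param models Transcript model table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    rows[[length(rows) + 1L]] <- data.table(
      chrom = models$chrom[i], start = ex[, 1L], end = ex[, 2L],
      strand = models$strand[i], type = "exon",
      gene_id = models$gene_id[i], transcript_id = models$tx_id[i],
      transcript_biotype = models$biotype[i])
  }
  dt <- rbindlist(rows)
  gr <- gr0(dt$chrom, dt$start, dt$end, dt$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lrcage", type = dt$type, gene_id = dt$gene_id,
    transcript_id = dt$transcript_id,
    transcript_biotype = dt$transcript_biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Import transcript models from a GTF file
#'
#' Reads exon features (via `rtracklayer`) and reassembles the
#' package's transcript model table.
#'
#' @param path GTF file.
#' @return A transcript model table.
#' @export
read_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  dt <- dt0(gr)
  dt$tx_id <- gr$transcript_id
  dt$gene_id <- gr$gene_id
  dt$biotype <- if ("transcript_biotype" %in% names(S4Vectors::mcols(gr)))
    gr$transcript_biotype else "protein_coding"
  by_tx <- split(dt, dt$tx_id)
  transcript_models(
    tx_id = names(by_tx),
    gene_id = vapply(by_tx, function(d) d$gene_id[1L], character(1)),
    chrom = vapply(by_tx, function(d) d$chrom[1L], character(1)),
    strand = vapply(by_tx, function(d) d$strand[1L], character(1)),
    exons = lapply(by_tx, function(d) exon_matrix(d$start, d$end)),
    biotype = vapply(by_tx, function(d) d$biotype[1L], character(1))
  )
}
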