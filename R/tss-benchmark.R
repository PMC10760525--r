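#' Criteria defining transcriptionally active annotated TSSs
#'
#' An annotated TSS is "active" when its transcript is protein-coding,
#' its length falls in the configured range, and both expression
#' quantifiers report at least the TPM floor (default 1 TPM by both; a
#' relaxed variant at 0.1 TPM is also conventional). The published
#' length range of 0.3-1 kbp is the literal default; `(300, Inf)` is a
#' documented alternative for analyses spanning long transcripts.
#'
#' @param require_protein_coding Restrict to protein-coding biotype.
#' @param transcript_length_range Numeric `(min, max)` in bp.
#' @param min_tpm_primary,min_tpm_secondary TPM floors for the two
#'   quantifiers.
#' @return List of class `active_gtss_criteria`.
#' @export
active_gtss_criteria <- function(require_protein_coding = TRUE,
                                 transcript_length_range = c(300, 1000),
                                 min_tpm_primary = 1, min_tpm_secondary = 1) {
  assert_that(transcript_length_range[1] > 0 &&
                transcript_length_range[2] >= transcript_length_range[1],
              "length range must satisfy 0 < min <= max")
  assert_that(min_tpm_primary >= 0 && min_tpm_secondary >= 0,
              "TPM thresholds must be >= 0")
  structure(list(require_protein_coding = isTRUE(require_protein_coding),
                 transcript_length_range = transcript_length_range,
                 min_tpm_primary = min_tpm_primary,
                 min_tpm_secondary = min_tpm_secondary),
            class = "active_gtss_criteria")
}

#' Define the active annotated-TSS set from annotation plus expression
#'
#' Applies [active_gtss_criteria()] to a transcript model table and two
#' expression tables (`tx_id`, `tpm`). Transcripts present in the
#' annotation but absent from an expression table are treated as 0 TPM
#' with a warning. Transcripts sharing an identical TSS position are
#' collapsed to one record keeping the maximum TPM.
#'
#' @param models Transcript model table.
#' @param expr_primary,expr_secondary data.tables with `tx_id`, `tpm`.
#' @param criteria An [active_gtss_criteria()] object.
#' @return data.table: `chrom`, `pos`, `strand`, `gene_id`, `tx_id`,
#'   `tx_length`, `tpm` (primary quantifier, max over collapsed
#'   transcripts).
#' @export
define_active_gtss <- function(models, expr_primary, expr_secondary,
                               criteria = active_gtss_criteria()) {
  stopifnot(inherits(criteria, "active_gtss_criteria"))
  dt <- as.data.table(models)
  lookup <- function(expr) {
    expr <- as.data.table(expr)
    tpm <- expr$tpm[match(dt$tx_id, expr$tx_id)]
    if (anyNA(tpm)) {
      warning(sprintf("%d transcript(s) missing from an expression table; treated as 0 TPM",
                      sum(is.na(tpm))))
      tpm[is.na(tpm)] <- 0
    }
    tpm
  }
  tpm1 <- lookup(expr_primary); tpm2 <- lookup(expr_secondary)
  keep <- tpm1 >= criteria$min_tpm_primary &
    tpm2 >= criteria$min_tpm_secondary &
    dt$tx_length >= criteria$transcript_length_range[1] &
    dt$tx_length <= criteria$transcript_length_range[2]
  if (criteria$require_protein_coding)
    keep <- keep & dt$biotype == "protein_coding"
  out <- dt[keep, .(chrom, pos = tss, strand, gene_id, tx_id, tx_length,
                    tpm = tpm1[keep])]
  if (nrow(out) == 0L) return(out[])
  setorder(out, chrom, strand, pos, -tpm)
  out <- out[!duplicated(out[, .(chrom, strand, pos)])]
  out[]
}

#' Benchmark a peak set against active TSSs with a tolerance window
#'
#' A TSS counts as detected when some same-strand peak, expanded by
#' `tolerance` bp on both sides, contains it; a peak counts as true
#' positive when it matches at least one active TSS the same way.
#' Recall = detected / total TSSs; precision = matching peaks / total
#' peaks; F-score is their harmonic mean (0 when both are 0).
#'
#' @param peaks Tag cluster or consensus peak table (`chrom`, `start`,
#'   `end`, `strand`).
#' @param active_gtss data.table with `chrom`, `pos`, `strand`.
#' @param tolerance Window in bp (default 200).
#' @return List of class `benchmark_result`: `n_peaks`,
#'   `n_active_gtss`, `precision`, `recall`, `f_score`, `tolerance`,
#'   `detected` (logical per TSS), `peak_matched` (logical per peak).
#' @export
benchmark_peaks <- function(peaks, active_gtss, tolerance = 200L) {
  pk <- as.data.table(peaks)
  ag <- as.data.table(active_gtss)
  assert_that(nrow(ag) > 0L, "empty active TSS set")
  if (nrow(pk) == 0L) {
    detected <- rep(FALSE, nrow(ag))
    return(structure(list(n_peaks = 0L, n_active_gtss = nrow(ag),
                          precision = 0, recall = 0, f_score = 0,
                          tolerance = tolerance, detected = detected,
                          peak_matched = logical(0)),
                     class = "benchmark_result"))
  }
  pg <- gr0(pk$chrom, pmax(0L, pk$start - tolerance), pk$end + tolerance,
            pk$strand)
  tg <- gr0(ag$chrom, ag$pos, ag$pos + 1L, ag$strand)
  hits <- GenomicRanges::findOverlaps(tg, pg, ignore.strand = FALSE)
  detected <- seq_len(nrow(ag)) %in% S4Vectors::queryHits(hits)
  peak_matched <- seq_len(nrow(pk)) %in% S4Vectors::subjectHits(hits)
  recall <- mean(detected)
  precision <- mean(peak_matched)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(n_peaks = nrow(pk), n_active_gtss = nrow(ag),
                 precision = precision, recall = recall, f_score = f,
                 tolerance = as.integer(tolerance), detected = detected,
                 peak_matched = peak_matched),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "benchmark: %d peaks vs %d active TSSs (±%d bp)\n  precision %.3f  recall %.3f  F %.3f\n",
    x$n_peaks, x$n_active_gtss, x$tolerance, x$precision, x$recall,
    x$f_score))
  invisible(x)
}

#' Rediscovery rate of a target TSS set from raw CTSS signal
#'
#' A target TSS is rediscovered when some same-strand CTSS position
#' within +/- `window` bp carries at least `min_reads` reads (a single
#' position must reach the read floor; counts are not summed across
#' positions).
#'
#' @param target_gtss data.table with `chrom`, `pos`, `strand`.
#' @param ctss CTSS table from one library.
#' @param min_reads Read floor per CTSS position (default 2).
#' @param window Tolerance in bp (default 200).
#' @return List: `rate`, `rediscovered` (logical per target).
#' @export
rediscovery_rate <- function(target_gtss, ctss, min_reads = 2L,
                             window = 200L) {
  tg <- as.data.table(target_gtss)
  assert_that(nrow(tg) > 0L, "empty target TSS set")
  cts <- as.data.table(ctss)[count >= min_reads]
  if (nrow(cts) == 0L)
    return(list(rate = 0, rediscovered = rep(FALSE, nrow(tg))))
  qg <- gr0(tg$chrom, pmax(0L, tg$pos - window), tg$pos + window + 1L,
            tg$strand)
  sg <- gr0(cts$chrom, cts$pos, cts$pos + 1L, cts$strand)
  hit <- IRanges::overlapsAny(qg, sg, ignore.strand = FALSE)
  list(rate = mean(hit), rediscovered = hit)
}

#' Recall stratified by expression, mappability, or transcript length
#'
#' Computes [benchmark_peaks()] recall within each stratum of the
#' active-TSS set. Strata are defined by cut points (`breaks`) on a
#' numeric column of `active_gtss`, or by an existing factor column.
#' Empty strata are reported as `NA` (undefined), not 0. The
#' size-weighted mean of stratum recalls equals the overall recall.
#'
#' @param peaks Peak table.
#' @param active_gtss Active TSS table carrying the stratification
#'   column.
#' @param column Name of the column to stratify on.
#' @param breaks Numeric cut points (ignored when the column is already
#'   a factor/character); must be strictly increasing.
#' @param tolerance Benchmark tolerance in bp.
#' @return data.table: `stratum`, `n`, `recall`.
#' @export
stratified_recall <- function(peaks, active_gtss, column, breaks = NULL,
                              tolerance = 200L) {
  ag <- as.data.table(active_gtss)
  assert_that(column %in% names(ag),
              sprintf("no column '%s' in active TSS table", column))
  x <- ag[[column]]
  if (is.numeric(x)) {
    assert_that(!is.null(breaks), "numeric stratification needs 'breaks'")
    assert_that(!is.unsorted(breaks, strictly = TRUE),
                "breaks must be strictly increasing (non-overlapping bins)")
    strat_f <- cut(x, breaks = breaks, include.lowest = TRUE)
  } else {
    strat_f <- factor(x)
  }
  bm <- benchmark_peaks(peaks, ag, tolerance)
  recall_by <- vapply(levels(strat_f), function(s) {
    idx <- which(strat_f == s)
    if (length(idx) == 0L) NA_real_ else mean(bm$detected[idx])
  }, numeric(1))
  data.table(stratum = levels(strat_f),
             n = as.integer(table(strat_f)),
             recall = recall_by)
}
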