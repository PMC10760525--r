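#' Filter transcript models by 5' peak support
#'
#' Retains a model only when its TSS lies within
#' `[peak.start - slack, peak.end + slack)` of a same-strand peak.
#' `slack = 0` reproduces strict containment.
#'
#' @param models Transcript model table.
#' @param peaks Peak table (`chrom`, `start`, `end`, `strand`).
#' @param slack Tolerance in bp around each peak (default 50).
#' @return The supported subset of `models`.
#' @export
filter_five_prime_support <- function(models, peaks, slack = 50L) {
  dt <- as.data.table(models)
  pk <- as.data.table(peaks)
  if (nrow(dt) == 0L) return(dt)
  if (nrow(pk) == 0L) return(dt[0L])
  q <- gr0(dt$chrom, dt$tss, dt$tss + 1L, dt$strand)
  s <- gr0(pk$chrom, pmax(0L, pk$start - slack), pk$end + slack, pk$strand)
  dt[IRanges::overlapsAny(q, s, ignore.strand = FALSE)]
}

#' Classify transcript novelty against a reference annotation
#'
#' Splice-chain comparison in the style of long-read isoform
#' classifiers:
#' * `known` - the junction chain exactly matches a reference
#'   transcript (mono-exonic models must match a mono-exonic reference
#'   exon exactly);
#' * `ISM` (incomplete splice match) - the chain is a contiguous
#'   sub-chain of a reference chain;
#' * `NIC` (novel in catalog) - every junction is individually known
#'   but the chain is novel;
#' * `NNC` (novel not in catalog) - at least one novel junction, with
#'   same-strand gene overlap;
#' * `antisense` - overlaps a gene on the opposite strand only;
#' * `intergenic` - overlaps no gene;
#' * `genomic` - mono-exonic within a gene without junction evidence.
#'
#' Classification is deterministic and independent of reference
#' ordering.
#'
#' @param models Transcript model table to classify.
#' @param annotation An [tx_annotation()] reference.
#' @return `models` with a `novelty_class` column.
#' @export
classify_novelty <- function(models, annotation) {
  stopifnot(inherits(annotation, "lrcage_annotation"))
  dt <- copy(as.data.table(models))
  if (nrow(dt) == 0L) { dt[, novelty_class := character(0)]; return(dt[]) }
  ref_chains <- annotation$ref_chains
  ## delimited on both sides so sub-chain matching cannot align across
  ## junction-key boundaries
  ref_chain_str <- vapply(ref_chains, function(ch)
    paste0("|", paste(ch, collapse = "|"), "|"), character(1))
  known_junctions <- unique(unlist(ref_chains, use.names = FALSE))
  ref_models <- annotation$models
  mono_ref <- ref_models[vapply(ref_models$exons, nrow, integer(1)) == 1L]
  genes <- annotation$genes
  cls <- character(nrow(dt))
  for (i in seq_len(nrow(dt))) {
    ex <- dt$exons[[i]]
    assert_that(all(diff(ex[, 1L]) > 0) || nrow(ex) == 1L,
                sprintf("model %s: unsorted exons", dt$tx_id[i]))
    chain <- junction_chain(dt$chrom[i], dt$strand[i], ex)
    g_same <- genes[chrom == dt$chrom[i] & strand == dt$strand[i] &
                      start < ex[nrow(ex), 2L] & end > ex[1L, 1L]]
    g_opp <- genes[chrom == dt$chrom[i] & strand != dt$strand[i] &
                     start < ex[nrow(ex), 2L] & end > ex[1L, 1L]]
    if (length(chain) == 0L) {
      match_mono <- nrow(mono_ref) > 0L && any(
        mono_ref$chrom == dt$chrom[i] & mono_ref$strand == dt$strand[i] &
          vapply(mono_ref$exons, function(e)
            e[1L, 1L] == ex[1L, 1L] && e[1L, 2L] == ex[1L, 2L], logical(1)))
      cls[i] <- if (match_mono) "known"
        else if (nrow(g_same)) "genomic"
        else if (nrow(g_opp)) "antisense"
        else "intergenic"
      next
    }
    chain_str <- paste0("|", paste(chain, collapse = "|"), "|")
    if (chain_str %in% ref_chain_str) { cls[i] <- "known"; next }
    is_sub <- any(vapply(ref_chain_str, function(r)
      grepl(chain_str, r, fixed = TRUE), logical(1)))
    if (is_sub) { cls[i] <- "ISM"; next }
    all_known <- all(chain %in% known_junctions)
    if (all_known) { cls[i] <- "NIC"; next }
    cls[i] <- if (nrow(g_same)) "NNC"
      else if (nrow(g_opp)) "antisense"
      else "intergenic"
  }
  dt[, novelty_class := cls]
  dt[]
}

#' Transcript-per-million quantification from read assignments
#'
#' Full-length long reads count one molecule each, so TPM here is the
#' read count divided by the total assigned count times 1e6, with no
#' length normalisation. TPM sums to 1e6 over all models.
#'
#' @param assignments data.table with `tx_id` (one row per assigned
#'   read) or precomputed `tx_id`, `count`.
#' @param models Optional model table; models without reads get 0 TPM.
#' @return data.table: `tx_id`, `count`, `tpm`.
#' @export
quantify_tpm <- function(assignments, models = NULL) {
  asn <- as.data.table(assignments)
  counts <- if ("count" %in% names(asn)) asn[, .(count = sum(count)), by = tx_id]
    else asn[, .(count = .N), by = tx_id]
  if (!is.null(models)) {
    all_tx <- as.data.table(models)$tx_id
    counts <- merge(data.table(tx_id = all_tx), counts, by = "tx_id",
                    all.x = TRUE)
    counts[is.na(count), count := 0L]
  }
  total <- sum(counts$count)
  assert_that(total > 0, "zero total assigned reads")
  counts[, tpm := count / total * 1e6]
  setorder(counts, tx_id)
  counts[]
}

#' Tag transcript models with TE class at the 5' end and LTR context
#'
#' `te_5prime_class` is the repeat class of the TE element containing
#' the model's TSS (`none` outside TEs; nested TEs resolve to the
#' smallest). For LTR-initiated models the `context` is classified with
#' precedence proviral > genic > unannotated: `proviral_HERV` when any
#' exon overlaps a proviral HERV interval, else `genic` when the model
#' overlaps an annotated gene on the same strand, else `unannotated`.
#' Non-LTR models get context `not_applicable`.
#'
#' @param models Transcript model table.
#' @param te_catalog TE catalog.
#' @param proviral data.table of proviral loci (`chrom`, `start`,
#'   `end`) or `NULL`.
#' @param annotation An [tx_annotation()] object.
#' @return `models` with `te_5prime_class` and `context` columns.
#' @export
tag_te_context <- function(models, te_catalog, proviral = NULL, annotation) {
  stopifnot(inherits(annotation, "lrcage_annotation"))
  dt <- copy(as.data.table(models))
  te <- as.data.table(te_catalog)
  dt[, te_5prime_class := "none"]
  dt[, te_5prime_id := NA_character_]
  dt[, context := "not_applicable"]
  if (nrow(dt) == 0L) return(dt[])
  if (nrow(te) > 0L) {
    q <- gr0(dt$chrom, dt$tss, dt$tss + 1L)
    s <- gr0(te$chrom, te$start, te$end)
    hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    if (length(hits)) {
      hdt <- data.table(m = S4Vectors::queryHits(hits),
                        t = S4Vectors::subjectHits(hits))
      hdt[, width := te$end[t] - te$start[t]]
      setorder(hdt, m, width, t)
      hdt <- hdt[!duplicated(m)]
      dt[hdt$m, `:=`(te_5prime_class = te$class_name[hdt$t],
                     te_5prime_id = te$te_id[hdt$t])]
    }
  }
  genes <- annotation$genes
  for (i in which(dt$te_5prime_class == "LTR")) {
    ex <- dt$exons[[i]]
    in_proviral <- FALSE
    if (!is.null(proviral) && nrow(proviral) > 0L) {
      q <- gr0(rep(dt$chrom[i], nrow(ex)), ex[, 1L], ex[, 2L])
      s <- gr0(proviral$chrom, proviral$start, proviral$end)
      in_proviral <- any(IRanges::overlapsAny(q, s, ignore.strand = TRUE))
    }
    g_same <- genes[chrom == dt$chrom[i] & strand == dt$strand[i] &
                      start < ex[nrow(ex), 2L] & end > ex[1L, 1L]]
    dt$context[i] <- if (in_proviral) "proviral_HERV"
      else if (nrow(g_same)) "genic" else "unannotated"
  }
  dt[]
}

#' Flag drug-induced transcripts
#'
#' A transcript is drug-induced when its treated-condition expression
#' reaches `min_tpm` (default 1 TPM) and its control expression is
#' exactly 0 TPM.
#'
#' @param tpm_treated,tpm_control Numeric vectors (recycled to common
#'   length).
#' @param min_tpm Treated-condition TPM floor.
#' @return Logical vector.
#' @export
call_drug_induced <- function(tpm_treated, tpm_control, min_tpm = 1) {
  assert_that(all(tpm_treated >= 0) && all(tpm_control >= 0),
              "TPM values must be nonnegative")
  tpm_treated >= min_tpm & tpm_control == 0
}
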