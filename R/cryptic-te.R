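#' Call cryptic TSSs
#'
#' A peak is a cryptic TSS when its dominant CTSS position lies at
#' least `min_distance` bp from every same-strand annotated TSS and its
#' interval overlaps no annotated exon on either strand (the
#' strand-agnostic exon exclusion is the conservative reading and
#' guards against incomplete reverse transcription artifacts).
#'
#' @param peaks Tag cluster table with `dominant_pos`.
#' @param annotation An [tx_annotation()] object.
#' @param min_distance Minimum distance to a same-strand annotated TSS
#'   (default 200 bp).
#' @return The subset of `peaks` that are cryptic.
#' @export
call_cryptic_tss <- function(peaks, annotation, min_distance = 200L) {
  stopifnot(inherits(annotation, "lrcage_annotation"))
  pk <- as.data.table(peaks)
  if (nrow(pk) == 0L) return(pk)
  tssdt <- annotation$tss
  far <- vapply(seq_len(nrow(pk)), function(i) {
    same <- tssdt[chrom == pk$chrom[i] & strand == pk$strand[i]]
    if (nrow(same) == 0L) return(TRUE)
    min(abs(same$pos - pk$dominant_pos[i])) >= min_distance
  }, logical(1))
  exons <- rbindlist(list(
    annotation$features$first_exon[, .(chrom, start, end)],
    annotation$features$other_exon[, .(chrom, start, end)],
    annotation$features$utr5[, .(chrom, start, end)],
    annotation$features$utr3[, .(chrom, start, end)]))
  no_exon <- if (nrow(exons) == 0L) rep(TRUE, nrow(pk)) else {
    q <- gr0(pk$chrom, pk$start, pk$end)
    s <- gr0(exons$chrom, exons$start, exons$end)
    !IRanges::overlapsAny(q, s, ignore.strand = TRUE)
  }
  pk[far & no_exon]
}

#' Assign cryptic peaks to containing TE elements, with orientation
#'
#' Each peak is assigned to the TE element that contains its dominant
#' CTSS position; nested TEs are resolved to the smallest containing
#' element. Orientation is `sense` when the peak strand matches the TE
#' strand, `antisense` otherwise; peaks outside every TE are labelled
#' `non-TE`.
#'
#' @param peaks Cryptic peak table with `dominant_pos`, `strand`.
#' @param te_catalog TE catalog: `te_id`, `chrom`, `start`, `end`,
#'   `strand`, `subfamily`, `family`, `class_name`, `substitutions`,
#'   `insertions`.
#' @return `peaks` with `te_id`, `subfamily`, `family`, `class_name`,
#'   `orientation` columns (`NA`/`"non-TE"` outside TEs).
#' @export
assign_te_overlap <- function(peaks, te_catalog) {
  pk <- copy(as.data.table(peaks))
  te <- as.data.table(te_catalog)
  n <- nrow(pk)
  pk[, `:=`(te_id = NA_character_, subfamily = NA_character_,
            family = NA_character_, class_name = NA_character_,
            orientation = "non-TE")]
  if (n == 0L || nrow(te) == 0L) return(pk[])
  q <- gr0(pk$chrom, pk$dominant_pos, pk$dominant_pos + 1L)
  s <- gr0(te$chrom, te$start, te$end)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (length(hits)) {
    hdt <- data.table(peak = S4Vectors::queryHits(hits),
                      ti = S4Vectors::subjectHits(hits))
    hdt[, width := te$end[ti] - te$start[ti]]
    setorder(hdt, peak, width, ti)
    hdt <- hdt[!duplicated(peak)]
    pk[hdt$peak, `:=`(te_id = te$te_id[hdt$ti],
                      subfamily = te$subfamily[hdt$ti],
                      family = te$family[hdt$ti],
                      class_name = te$class_name[hdt$ti],
                      orientation = ifelse(strand == te$strand[hdt$ti],
                                           "sense", "antisense"))]
  }
  pk[]
}

#' Subfamily enrichment of TEs among cryptic TSSs
#'
#' For grouping level `s` (subfamily by default), the enrichment score
#' is the observed/expected element-count ratio
#' `(o_s / O) / (n_s / N)`, where `o_s` is the number of catalog
#' elements of group `s` overlapping cryptic TSSs, `O` the number of
#' elements of any group doing so, `n_s` the catalog size of `s`, and
#' `N` the catalog total. A group is called enriched when the score is
#' at least `min_score` (default 1.5), the catalog holds at least
#' `min_elements` elements (default 100), and at least `min_overlap`
#' elements overlap cryptic TSSs (default 5). The same formula applies
#' to class- or clade-level grouping.
#'
#' @param assignments Output of [assign_te_overlap()] (TE-assigned
#'   cryptic peaks).
#' @param te_catalog Full TE catalog.
#' @param group Catalog column to group by (default `"subfamily"`).
#' @param min_score,min_elements,min_overlap Enrichment thresholds.
#' @return data.table: group value, `n_elements`, `n_overlapping`,
#'   `enrichment_score`, `is_enriched`.
#' @export
compute_enrichment <- function(assignments, te_catalog, group = "subfamily",
                               min_score = 1.5, min_elements = 100L,
                               min_overlap = 5L) {
  asn <- as.data.table(assignments)
  te <- as.data.table(te_catalog)
  assert_that(group %in% names(te), sprintf("no column '%s' in catalog", group))
  hit_tes <- unique(asn$te_id[!is.na(asn$te_id)])
  O <- length(hit_tes)
  assert_that(O > 0L, "no TE elements overlap cryptic TSSs")
  N <- nrow(te)
  te[, .hit := te_id %in% hit_tes]
  out <- te[, .(n_elements = .N, n_overlapping = sum(.hit)), by = group]
  te[, .hit := NULL]
  out[, enrichment_score := (n_overlapping / O) / (n_elements / N)]
  out[, is_enriched := enrichment_score >= min_score &
        n_elements >= min_elements & n_overlapping >= min_overlap]
  setorder(out, -enrichment_score)
  out[]
}

#' Estimate TE evolutionary age from divergence
#'
#' Divergence is the substitution count against the subfamily consensus
#' divided by the genomic element length minus inserted bases; age is
#' divergence divided by the neutral substitution rate (default 2.2e-9
#' substitutions per site per year).
#'
#' @param substitutions,length,insertions Integer vectors (recycled).
#' @param subst_rate Neutral rate per site per year.
#' @return Numeric vector of ages in years.
#' @examples
#' estimate_te_age(11, 1000, 0)   # 1.1% divergence -> 5e6 years
#' @export
estimate_te_age <- function(substitutions, length, insertions = 0L,
                            subst_rate = 2.2e-9) {
  assert_that(all(substitutions >= 0) && all(insertions >= 0),
              "substitutions and insertions must be >= 0")
  denom <- length - insertions
  assert_that(all(denom > 0), "length minus insertions must be positive")
  assert_that(subst_rate > 0, "substitution rate must be positive")
  (substitutions / denom) / subst_rate
}
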