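#' Protocol-specific preprocessing rules
#'
#' Encodes the per-protocol trimming and alignment-filter thresholds:
#' trimmed reads must be at least 250 bp to count as full-length
#' nonchimeric (long-read protocols); up to 15 terminal A's are trimmed
#' for LRCAGE only; aligned reads with more than three soft-clipped
#' bases at either end (LRCAGE) or more than three at the 5' end /
#' twenty at the 3' end (LRhex) are discarded. nanoCAGE reads are short,
#' so they get a lower length floor and no soft-clip filter.
#'
#' @param protocol `"LRCAGE"`, `"LRhex"`, or `"nanoCAGE"`.
#' @param config A [pipeline_config()].
#' @return A list of class `protocol_rules`.
#' @export
protocol_rules <- function(protocol = c("LRCAGE", "LRhex", "nanoCAGE"),
                           config = pipeline_config()) {
  protocol <- match.arg(protocol)
  rules <- list(
    protocol = protocol,
    min_trimmed_length = if (protocol == "nanoCAGE")
      config$nanocage_min_length else config$min_trimmed_length,
    polya_trim = if (protocol == "LRCAGE") config$polya_trim else 0L,
    max_clip5 = if (protocol == "nanoCAGE") Inf else config$max_clip5,
    max_clip3 = switch(protocol,
                       LRCAGE = config$max_clip3_lrcage,
                       LRhex = config$max_clip3_lrhex,
                       nanoCAGE = Inf),
    tso_linker = config$tso_linker,
    umi_length = config$umi_length,
    tso_spacer = config$tso_spacer
  )
  structure(rules, class = "protocol_rules")
}

#' Trim the TSO prefix (and LRCAGE poly(A) tail) from raw reads
#'
#' Locates the template-switching-oligo prefix (linker + UMI + spacer)
#' at the read 5' end, captures the UMI, removes the prefix, trims up to
#' `polya_trim` terminal A's (LRCAGE only), and rejects reads whose
#' trimmed length falls below the protocol's minimum. Rejection reasons
#' are `"no_tso"` and `"too_short"`.
#'
#' @param sequences Character vector of raw read sequences.
#' @param rules A [protocol_rules()] object.
#' @return A data.table with columns `sequence` (trimmed; `NA` when
#'   rejected), `umi`, `status` (`"ok"`/`"rejected"`), `reason`.
#' @export
trim_read <- function(sequences, rules) {
  stopifnot(inherits(rules, "protocol_rules"))
  assert_that(all(nzchar(sequences)), "read sequences must be nonempty")
  linker <- rules$tso_linker; spacer <- rules$tso_spacer
  lw <- nchar(linker); uw <- rules$umi_length; sw <- nchar(spacer)
  has_linker <- substr(sequences, 1L, lw) == linker
  has_spacer <- substr(sequences, lw + uw + 1L, lw + uw + sw) == spacer
  ok_tso <- has_linker & has_spacer
  umi <- ifelse(ok_tso, substr(sequences, lw + 1L, lw + uw), NA_character_)
  insert <- ifelse(ok_tso, substr(sequences, lw + uw + sw + 1L,
                                  nchar(sequences)), NA_character_)
  if (rules$polya_trim > 0L) {
    trailing <- nchar(insert) - nchar(sub("A*$", "", insert))
    cut <- pmin(trailing, rules$polya_trim)
    insert <- ifelse(ok_tso & !is.na(insert),
                     substr(insert, 1L, nchar(insert) - cut), insert)
  }
  too_short <- ok_tso & nchar(insert) < rules$min_trimmed_length
  status <- ifelse(!ok_tso, "rejected", ifelse(too_short, "rejected", "ok"))
  reason <- ifelse(!ok_tso, "no_tso", ifelse(too_short, "too_short", NA))
  data.table(sequence = ifelse(status == "ok", insert, NA_character_),
             umi = umi, status = status, reason = reason)
}

#' Filter aligned reads by mapping flags and soft-clip thresholds
#'
#' Partitions an alignment table into kept and discarded reads without
#' altering any alignment. Reads are discarded, with an enumerated
#' reason, when they are secondary, supplementary, or multimapping, or
#' when a soft-clip count exceeds the protocol threshold (checked 5'
#' end first). Soft-clip counts are read-strand relative: for a
#' minus-strand read, `clip5` is the rightmost genomic clip.
#'
#' @param alignments Alignment table: one row per aligned read with
#'   columns `read_id`, `chrom`, `strand`, `blocks` (list of two-column
#'   0-based half-open matrices), `clip5`, `clip3`, `umi`, `mapq`,
#'   `is_primary`, `is_supplementary`, `is_unique`.
#' @param rules A [protocol_rules()] object.
#' @return A list with `kept` (alignment table), and `audit` (read_id,
#'   decision, reason).
#' @export
filter_alignment <- function(alignments, rules) {
  stopifnot(inherits(rules, "protocol_rules"))
  aln <- as.data.table(alignments)
  if (!"is_unique" %in% names(aln) || anyNA(aln$is_unique)) {
    warning("alignments lack a uniqueness flag; treating as unique")
    if (!"is_unique" %in% names(aln)) aln$is_unique <- TRUE
    aln[is.na(is_unique), is_unique := TRUE]
  }
  reason <- rep(NA_character_, nrow(aln))
  reason[!aln$is_primary] <- "secondary"
  reason[is.na(reason) & aln$is_supplementary] <- "supplementary"
  reason[is.na(reason) & !aln$is_unique] <- "multimapper"
  reason[is.na(reason) & aln$clip5 > rules$max_clip5] <- "clip5"
  reason[is.na(reason) & aln$clip3 > rules$max_clip3] <- "clip3"
  keep <- is.na(reason)
  list(kept = aln[keep],
       audit = data.table(read_id = aln$read_id,
                          decision = ifelse(keep, "keep", "discard"),
                          reason = reason))
}

aln_end5 <- function(aln) {
  s <- vapply(aln$blocks, function(b) b[1L, 1L], integer(1))
  e <- vapply(aln$blocks, function(b) b[nrow(b), 2L], integer(1))
  ifelse(aln$strand == "+", s, e - 1L)
}

aln_end3 <- function(aln) {
  s <- vapply(aln$blocks, function(b) b[1L, 1L], integer(1))
  e <- vapply(aln$blocks, function(b) b[nrow(b), 2L], integer(1))
  ifelse(aln$strand == "+", e - 1L, s)
}

#' Deduplicate alignments by coordinates and UMI
#'
#' Keeps one representative per (chrom, strand, 5'-end, 3'-end, UMI)
#' key: the highest-mapping-quality, then lexicographically smallest,
#' read id. UMIs must match exactly; reads with the same coordinates
#' but different UMIs are distinct molecules and are both retained.
#' The output is sorted by coordinates and read id, so it does not
#' depend on input order, and the operation is idempotent.
#'
#' @param alignments Alignment table (see [filter_alignment()]).
#' @return Deduplicated alignment table.
#' @export
deduplicate <- function(alignments) {
  aln <- as.data.table(alignments)
  if (nrow(aln) == 0L) return(aln)
  aln[, `:=`(.e5 = aln_end5(aln), .e3 = aln_end3(aln))]
  if (!"umi" %in% names(aln)) aln$umi <- ""
  aln[is.na(umi), umi := ""]
  ord <- order(aln$chrom, aln$strand, aln$.e5, aln$.e3, aln$umi,
               -aln$mapq, aln$read_id)
  aln <- aln[ord]
  keep <- !duplicated(aln[, .(chrom, strand, .e5, .e3, umi)])
  out <- aln[keep]
  out[, c(".e5", ".e3") := NULL]
  out[]
}
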