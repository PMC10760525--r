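#' Classify an MS-identified peptide against reference and custom
#' proteomes
#'
#' A peptide is `canonical` when it occurs verbatim (100% identity;
#' isoleucine and leucine are not equated unless `collapse_il`) in the
#' reference proteome. Otherwise it is noncanonical:
#' `noncanonical_te` when every custom-proteome protein containing it
#' places every occurrence within or overlapping a TE-coded residue
#' range, `noncanonical_non_te` otherwise (the most conservative
#' category wins when sources disagree). Peptides absent from the
#' custom proteome entirely are flagged `unmatched` rather than
#' erroring.
#'
#' @param peptides Character vector of peptide sequences (>= 8 aa).
#' @param ref_proteome data.table with `sequence` (reference proteins).
#' @param custom_proteome A proteome table from
#'   [build_custom_proteome()] with `te_ranges`.
#' @param collapse_il Treat I and L as equivalent (default `FALSE`).
#' @return data.table: `sequence`, `category` (`canonical`,
#'   `noncanonical_te`, `noncanonical_non_te`, `unmatched`),
#'   `source_proteins` (comma-separated ids), `n_sources`.
#' @export
classify_peptide <- function(peptides, ref_proteome, custom_proteome,
                             collapse_il = FALSE) {
  assert_that(all(nchar(peptides) >= 8L),
              "peptides must be at least 8 aa long")
  assert_that(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides)),
              "peptides must use the 20-letter amino-acid alphabet")
  ref <- as.data.table(ref_proteome)
  cp <- as.data.table(custom_proteome)
  norm <- function(x) if (collapse_il) gsub("I", "L", x) else x
  ref_seqs <- norm(ref$sequence)
  cp_seqs <- norm(cp$sequence)
  res <- lapply(norm(peptides), function(pep) {
    canonical <- any(vapply(ref_seqs, grepl, logical(1), pattern = pep,
                            fixed = TRUE, USE.NAMES = FALSE))
    src <- which(vapply(cp_seqs, grepl, logical(1), pattern = pep,
                        fixed = TRUE, USE.NAMES = FALSE))
    if (canonical) {
      cat_lab <- "canonical"
    } else if (length(src) == 0L) {
      cat_lab <- "unmatched"
    } else {
      all_te <- all(vapply(src, function(s) {
        ranges <- cp$te_ranges[[s]]
        if (is.null(ranges) || nrow(ranges) == 0L) return(FALSE)
        occ <- gregexpr(pep, cp_seqs[s], fixed = TRUE)[[1]]
        all(vapply(occ, function(a) {
          b <- a + nchar(pep) - 1L
          any(ranges[, "start"] <= b & ranges[, "end"] >= a)
        }, logical(1)))
      }, logical(1)))
      cat_lab <- if (all_te) "noncanonical_te" else "noncanonical_non_te"
    }
    list(category = cat_lab,
         source_proteins = paste(cp$protein_id[src], collapse = ","),
         n_sources = length(src))
  })
  data.table(sequence = peptides,
             category = vapply(res, `[[`, character(1), "category"),
             source_proteins = vapply(res, `[[`, character(1),
                                      "source_proteins"),
             n_sources = vapply(res, `[[`, integer(1), "n_sources"))
}

#' Attach per-condition expression to peptide records
#'
#' Sums the TPM of every transcript encoding each peptide (per
#' condition) and computes the TE-transcript expression share
#' (`te_fraction`, defined only when total expression is positive).
#' A transcript counts as a TE transcript when its 5' end lies in a TE
#' (`te_5prime_class != "none"`).
#'
#' @param records Peptide classification table ([classify_peptide()]).
#' @param custom_proteome Proteome table (maps proteins to `tx_id`).
#' @param expression data.table: `tx_id`, `tpm_control`, `tpm_treated`,
#'   `is_te_transcript`.
#' @return `records` with `tpm_control`, `tpm_treated`, `te_fraction`
#'   columns.
#' @export
peptide_expression <- function(records, custom_proteome, expression) {
  rec <- copy(as.data.table(records))
  cp <- as.data.table(custom_proteome)
  ex <- as.data.table(expression)
  rec[, `:=`(tpm_control = 0, tpm_treated = 0, te_fraction = NA_real_)]
  for (i in seq_len(nrow(rec))) {
    ids <- strsplit(rec$source_proteins[i], ",", fixed = TRUE)[[1]]
    tx <- unique(cp$tx_id[cp$protein_id %in% ids])
    tx <- tx[!is.na(tx)]
    if (!length(tx)) next
    e <- ex[tx_id %in% tx]
    rec$tpm_control[i] <- sum(e$tpm_control)
    rec$tpm_treated[i] <- sum(e$tpm_treated)
    tot <- rec$tpm_control[i] + rec$tpm_treated[i]
    if (tot > 0)
      rec$te_fraction[i] <-
        sum(e$tpm_control[e$is_te_transcript] +
              e$tpm_treated[e$is_te_transcript]) / tot
  }
  rec[]
}

#' Flag drug-induced TE antigens
#'
#' A peptide record is flagged when it was detected under treatment but
#' not in the control, more than `min_te_fraction` of its expression
#' comes from TE transcripts, and its expression changed more than
#' `min_fold`-fold (control TPM of 0 yields infinite fold and passes).
#' A record detected with 0 treated TPM is an inconsistency error.
#'
#' @param detected_treated,detected_control Logical vectors.
#' @param tpm_treated,tpm_control Numeric vectors.
#' @param te_fraction Numeric vector in [0,1] (`NA` allowed when
#'   expression is absent; such records are never flagged).
#' @param min_te_fraction Strict lower bound on the TE share (default
#'   0.9).
#' @param min_fold Strict lower bound on the fold change (default 10).
#' @return Logical vector.
#' @export
call_drug_induced_te_antigen <- function(detected_treated, detected_control,
                                         tpm_treated, tpm_control,
                                         te_fraction,
                                         min_te_fraction = 0.9,
                                         min_fold = 10) {
  n <- length(detected_treated)
  assert_that(all(lengths(list(detected_control, tpm_treated, tpm_control,
                               te_fraction)) == n),
              "all argument vectors must have equal length")
  if (any(detected_treated & tpm_treated == 0))
    stop("peptide detected under treatment with 0 treated TPM: inconsistent inputs",
         call. = FALSE)
  fold <- ifelse(tpm_control == 0, Inf, tpm_treated / tpm_control)
  out <- detected_treated & !detected_control &
    !is.na(te_fraction) & te_fraction > min_te_fraction & fold > min_fold
  out
}

#' Tally antigen categories
#'
#' Deterministic category-by-condition counts; unmatched peptides are
#' reported separately. Invariant under record permutation.
#'
#' @param records Peptide table with `category` and logical
#'   `detected_control`/`detected_treated` columns (the detection
#'   columns are optional).
#' @return data.table: `category`, `n`, and where detection columns are
#'   present `n_control`, `n_treated`.
#' @export
summarize_antigens <- function(records) {
  rec <- as.data.table(records)
  cats <- c("canonical", "noncanonical_non_te", "noncanonical_te",
            "unmatched")
  out <- data.table(category = cats)
  if (nrow(rec) == 0L) {
    out[, n := 0L]
    return(out[])
  }
  out[, n := vapply(cats, function(cc) sum(rec$category == cc), integer(1))]
  if (all(c("detected_control", "detected_treated") %in% names(rec))) {
    out[, n_control := vapply(cats, function(cc)
      sum(rec$category == cc & rec$detected_control), integer(1))]
    out[, n_treated := vapply(cats, function(cc)
      sum(rec$category == cc & rec$detected_treated), integer(1))]
  }
  out[]
}
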