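#' Pipeline configuration
#'
#' Collects every numeric threshold used across the toolkit in one
#' validated object. Defaults are the published operating points of the
#' protocol: 250-bp minimum trimmed read length, 15-A poly(A) trim
#' (LRCAGE only), soft-clip limits of 3 (and 20 at the LRhex 3' end),
#' 0.35 cap-signal cutoff, 200-bp benchmark tolerance, two supporting
#' reads within a 200-bp rediscovery window, 1-TPM active-TSS cutoffs
#' (0.1 relaxed), 0.5 low-mappability threshold, subfamily enrichment at
#' (1.5, 100, 5), neutral substitution rate 2.2e-9 per year, 100-aa
#' minimum ORF, 25-aa three-frame peptides, 50-nt NMD rule, fourfold
#' peak up-regulation, 1-TPM drug induction, 0.9 TE expression fraction,
#' and 10-fold antigen induction.
#'
#' @param ... Named overrides for any default listed below.
#' @return An object of class `lrcage_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(cap_cutoff = 0.4)
#' cfg$cap_cutoff
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ## read QC
    min_trimmed_length = 250L,
    nanocage_min_length = 20L,
    polya_trim = 15L,
    max_clip5 = 3L,
    max_clip3_lrcage = 3L,
    max_clip3_lrhex = 20L,
    tso_linker = "AAGCAGTGGTATCAACGCAGAGT",
    umi_length = 8L,
    tso_spacer = "TATAGGG",
    ## CTSS / peaks
    paraclu_min_stability = 2,
    paraclu_max_length = 500L,
    paraclu_min_count = 2L,
    cap_cutoff = 0.35,
    cap_g_rate = 0.9,
    promoter_upstream = 500L,
    promoter_downstream = 100L,
    peak_min_fold = 4,
    peak_pseudocount = 1,
    ## benchmark
    tolerance = 200L,
    rediscovery_min_reads = 2L,
    rediscovery_window = 200L,
    min_tpm_primary = 1,
    min_tpm_secondary = 1,
    relaxed_min_tpm = 0.1,
    transcript_length_min = 300L,
    transcript_length_max = 1000L,
    ## mappability
    mappability_k = 50L,
    low_mappability = 0.5,
    tss_flank = 100L,
    ## cryptic TSS / TE
    cryptic_min_distance = 200L,
    enrichment_min_score = 1.5,
    enrichment_min_elements = 100L,
    enrichment_min_overlap = 5L,
    subst_rate = 2.2e-9,
    ## transcripts
    five_prime_slack = 50L,
    induced_min_tpm = 1,
    ## proteome
    min_orf_aa = 100L,
    three_frame_min_aa = 25L,
    nmd_rule_nt = 50L,
    classify_min_block = 10L,
    ## antigens
    min_te_fraction = 0.9,
    antigen_min_fold = 10,
    collapse_il = FALSE,
    ## run
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    assert_that(length(bad) == 0L,
                paste("unknown config fields:", paste(bad, collapse = ", ")))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "lrcage_config")
}

validate_config <- function(cfg) {
  num_pos <- c("min_trimmed_length", "nanocage_min_length", "polya_trim",
               "umi_length", "paraclu_min_stability", "paraclu_max_length",
               "paraclu_min_count", "tolerance", "rediscovery_min_reads",
               "rediscovery_window", "mappability_k", "tss_flank",
               "cryptic_min_distance", "enrichment_min_score",
               "enrichment_min_elements", "enrichment_min_overlap",
               "subst_rate", "five_prime_slack", "min_orf_aa",
               "three_frame_min_aa", "classify_min_block", "peak_min_fold",
               "antigen_min_fold")
  for (f in num_pos)
    assert_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] > 0,
                sprintf("config field '%s' must be a positive number", f))
  for (f in c("max_clip5", "max_clip3_lrcage", "max_clip3_lrhex", "nmd_rule_nt"))
    assert_that(is.numeric(cfg[[f]]) && cfg[[f]] >= 0,
                sprintf("config field '%s' must be non-negative", f))
  for (f in c("cap_cutoff", "cap_g_rate", "low_mappability", "min_te_fraction"))
    assert_that(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
                sprintf("config field '%s' must lie in [0, 1]", f))
  assert_that(cfg$transcript_length_min > 0 &&
                cfg$transcript_length_max >= cfg$transcript_length_min,
              "transcript length range must satisfy 0 < min <= max")
  assert_that(grepl("^[ACGT]+$", cfg$tso_linker) &&
                grepl("^[ACGT]+$", cfg$tso_spacer),
              "TSO linker and spacer must be ACGT strings")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param cfg An `lrcage_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns an `lrcage_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lrcage_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_fields <- c("min_trimmed_length", "nanocage_min_length", "polya_trim",
                  "max_clip5", "max_clip3_lrcage", "max_clip3_lrhex",
                  "umi_length", "paraclu_max_length", "paraclu_min_count",
                  "promoter_upstream", "promoter_downstream", "tolerance",
                  "rediscovery_min_reads", "rediscovery_window",
                  "transcript_length_min", "transcript_length_max",
                  "mappability_k", "tss_flank", "cryptic_min_distance",
                  "enrichment_min_elements", "enrichment_min_overlap",
                  "five_prime_slack", "min_orf_aa", "three_frame_min_aa",
                  "nmd_rule_nt", "classify_min_block", "seed")
  for (f in intersect(int_fields, names(vals))) vals[[f]] <- as.integer(vals[[f]])
  do.call(pipeline_config, vals)
}

#' @export
print.lrcage_config <- function(x, ...) {
  cat("lrcage pipeline configuration\n")
  for (n in names(x)) cat(sprintf("  %-24s %s\n", n, format(x[[n]])))
  invisible(x)
}
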