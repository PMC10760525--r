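#' Run the full pipeline on the synthetic fixture
#'
#' Orchestrates every stage in dependency order on generated data:
#' fixture generation, per-condition read simulation, TSO trimming,
#' alignment filtering and UMI deduplication, CTSS extraction, paraclu
#' peak calling, cap-signal filtering, peak annotation, consensus
#' merging and fold-change up-regulation, mappability, active-TSS
#' benchmarking with rediscovery and stratified recall, cryptic TSS
#' and TE analysis, transcript filtering/classification/quantification,
#' proteome construction, and antigen classification. Re-running with
#' the same config (and therefore seed) is bit-identical.
#'
#' @param config An [pipeline_config()] object, or a named list of
#'   overrides (validated here).
#' @param spec Optional [toy_genome_spec()]; defaults to the standard
#'   fixture built from `config$seed`.
#' @param protocol Read protocol for the simulated libraries.
#' @param depth,noise Passed to [simulate_cage_reads()].
#' @param out_dir Optional directory; when given, stage outputs and a
#'   JSON run manifest are written there (partial outputs are removed
#'   on failure).
#' @return A list of stage artifacts (class `lrcage_run`): `truth`,
#'   `ctss`, `peaks`, `consensus`, `upregulated`, `benchmark`,
#'   `rediscovery`, `stratified`, `mappability`, `active_gtss`,
#'   `cryptic`, `te_assignments`, `enrichment`, `transcripts`,
#'   `expression`, `proteome`, `antigens`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), spec = NULL,
                         protocol = "LRCAGE", depth = 3L, noise = 0,
                         out_dir = NULL) {
  if (!inherits(config, "lrcage_config"))
    config <- do.call(pipeline_config, as.list(config))
  if (is.null(spec)) spec <- toy_genome_spec(seed = config$seed)

  ref <- make_toy_reference(spec, config)
  truth <- ref$truth
  genome <- ref$genome
  rules <- protocol_rules(protocol, config)
  ann <- tx_annotation(ref$annotation, config$promoter_upstream,
                       config$promoter_downstream)

  per_cond <- list()
  for (cond in c("control", "treated")) {
    sim <- simulate_cage_reads(truth, protocol, depth = depth, noise = noise,
                               condition = cond)
    trm <- trim_read(sim$reads$sequence, rules)
    kept_ids <- sim$reads$read_id[trm$status == "ok"]
    aln <- sim$alignments[read_id %in% kept_ids]
    filt <- filter_alignment(aln, rules)
    dedup <- deduplicate(filt$kept)
    ctss <- extract_ctss(dedup)
    raw_peaks <- paraclu_cluster(ctss,
                                 min_stability = config$paraclu_min_stability,
                                 max_length = config$paraclu_max_length,
                                 min_count = config$paraclu_min_count)
    capped <- cap_signal_filter(raw_peaks, dedup, genome,
                                cutoff = config$cap_cutoff)
    asn <- sim$read_truth[read_id %in% dedup$read_id, .(read_id, tx_id)]
    per_cond[[cond]] <- list(sim = sim, trim = trm, dedup = dedup,
                             ctss = ctss, peaks = capped$kept,
                             peak_audit = capped$audit, assignments = asn)
  }

  peaks_trt <- annotate_peaks(per_cond$treated$peaks, ann)
  peaks_ctl <- annotate_peaks(per_cond$control$peaks, ann)

  consensus <- merge_consensus_peaks(
    list(control = peaks_ctl, treated = peaks_trt),
    ctss_sets = list(control = per_cond$control$ctss,
                     treated = per_cond$treated$ctss))
  upreg <- call_upregulated_peaks(consensus, consensus$count_treated,
                                  consensus$count_control,
                                  min_fold = config$peak_min_fold,
                                  pseudocount = config$peak_pseudocount)

  track <- compute_mappability(genome, k = config$mappability_k)

  expr_tbl <- truth$expression[, .(tx_id, tpm = tpm_treated)]
  active <- define_active_gtss(
    ref$annotation, expr_tbl, expr_tbl,
    active_gtss_criteria(
      transcript_length_range = c(config$transcript_length_min,
                                  config$transcript_length_max),
      min_tpm_primary = config$min_tpm_primary,
      min_tpm_secondary = config$min_tpm_secondary))
  active[, mappability := tss_mappability(track, active,
                                          flank = config$tss_flank)]

  tpm_trt <- truth$expression$tpm_treated[
    match(truth$true_tss$tx_id, truth$expression$tx_id)]
  true_tss_trt <- truth$true_tss[tpm_trt > 0]
  bench <- benchmark_peaks(peaks_trt, true_tss_trt,
                           tolerance = config$tolerance)
  redisc <- rediscovery_rate(active, per_cond$treated$ctss,
                             min_reads = config$rediscovery_min_reads,
                             window = config$rediscovery_window)
  strat <- stratified_recall(peaks_trt, active, column = "mappability",
                             breaks = c(0, config$low_mappability, 1),
                             tolerance = config$tolerance)

  cryptic <- call_cryptic_tss(peaks_trt, ann,
                              min_distance = config$cryptic_min_distance)
  te_asn <- assign_te_overlap(cryptic, ref$te_catalog)
  enrich <- if (any(!is.na(te_asn$te_id)))
    compute_enrichment(te_asn, ref$te_catalog,
                       min_score = config$enrichment_min_score,
                       min_elements = config$enrichment_min_elements,
                       min_overlap = config$enrichment_min_overlap)
    else NULL

  ## transcript stage: candidate models are the truth transcripts, as a
  ## long-read assembler would emit them
  models <- filter_five_prime_support(truth$models, peaks_trt,
                                      slack = config$five_prime_slack)
  models <- classify_novelty(models, ann)
  models <- tag_te_context(models, ref$te_catalog, truth$proviral, ann)
  q_trt <- quantify_tpm(per_cond$treated$assignments, models)
  q_ctl <- quantify_tpm(per_cond$control$assignments, models)
  models[, tpm_treated := q_trt$tpm[match(tx_id, q_trt$tx_id)]]
  models[, tpm_control := q_ctl$tpm[match(tx_id, q_ctl$tx_id)]]
  models[, drug_induced := call_drug_induced(tpm_treated, tpm_control,
                                             min_tpm = config$induced_min_tpm)]

  ## proteome stage
  cds_iv <- ref$annotation[!is.na(cds_start),
                           .(chrom, start = cds_start, end = cds_end)]
  novel_models <- models[novelty_class != "known"]
  novel_prot <- list()
  for (i in seq_len(nrow(novel_models))) {
    m <- novel_models[i]
    seq <- transcript_sequence(genome, m$chrom, m$exons[[1L]], m$strand)
    orf <- find_longest_orf(seq, min_aa = config$min_orf_aa)
    if (is.null(orf)) next
    if (!nmd_filter(m$exons[[1L]], m$strand, orf,
                    rule_nt = config$nmd_rule_nt)) next
    ranges <- te_coded_ranges(m$exons[[1L]], m$strand, m$chrom, orf,
                              ref$te_catalog)
    overlaps_cds <- nrow(cds_iv) > 0L && any(
      cds_iv$chrom == m$chrom & cds_iv$start < m$exons[[1L]][nrow(m$exons[[1L]]), 2L] &
        cds_iv$end > m$exons[[1L]][1L, 1L])
    gene_ctx <- if (m$gene_id %in% truth$ref_proteome$gene_id) m$gene_id
      else NA_character_
    cls <- classify_protein(orf$protein, truth$ref_proteome,
                            gene_id = gene_ctx, overlaps_cds = overlaps_cds,
                            min_block = config$classify_min_block)
    novel_prot[[length(novel_prot) + 1L]] <- data.table(
      sequence = orf$protein, gene_id = m$gene_id, tx_id = m$tx_id,
      class = cls, te_ranges = list(ranges))
  }
  novel_dt <- if (length(novel_prot)) rbindlist(novel_prot) else
    data.table(sequence = character(), gene_id = character(),
               tx_id = character(), class = character(), te_ranges = list())
  proteome <- build_custom_proteome(novel_dt, truth$ref_proteome)

  ## antigen stage
  peptides <- truth$planted_peptides
  antigens <- classify_peptide(peptides$sequence, truth$ref_proteome,
                               proteome, collapse_il = config$collapse_il)
  antigens[, `:=`(peptide_id = peptides$peptide_id,
                  detected_control = peptides$detected_control,
                  detected_treated = peptides$detected_treated)]
  expr_meas <- models[, .(tx_id, tpm_control, tpm_treated,
                          is_te_transcript = te_5prime_class != "none")]
  antigens <- peptide_expression(antigens, proteome, expr_meas)
  antigens[, drug_induced_te := FALSE]
  idx_te <- which(antigens$category == "noncanonical_te")
  if (length(idx_te))
    antigens$drug_induced_te[idx_te] <- call_drug_induced_te_antigen(
      antigens$detected_treated[idx_te], antigens$detected_control[idx_te],
      antigens$tpm_treated[idx_te], antigens$tpm_control[idx_te],
      antigens$te_fraction[idx_te],
      min_te_fraction = config$min_te_fraction,
      min_fold = config$antigen_min_fold)
  summary_tbl <- summarize_antigens(antigens)

  manifest <- list(
    config = unclass(config),
    config_md5 = config_md5(config),
    spec = unclass(spec),
    protocol = protocol, depth = depth, noise = noise,
    stage_counts = list(
      reads_control = nrow(per_cond$control$sim$reads),
      reads_treated = nrow(per_cond$treated$sim$reads),
      dedup_control = nrow(per_cond$control$dedup),
      dedup_treated = nrow(per_cond$treated$dedup),
      ctss_treated = nrow(per_cond$treated$ctss),
      peaks_treated = nrow(peaks_trt),
      consensus = nrow(consensus),
      upregulated = sum(upreg$upregulated),
      active_gtss = nrow(active),
      cryptic = nrow(cryptic),
      transcripts_retained = nrow(models),
      novel_transcripts = sum(models$novelty_class != "known"),
      drug_induced_transcripts = sum(models$drug_induced),
      proteins = nrow(proteome),
      novel_proteins = sum(proteome$source == "novel"),
      antigens = nrow(antigens),
      drug_induced_te_antigens = sum(antigens$drug_induced_te)),
    benchmark = list(precision = bench$precision, recall = bench$recall,
                     f_score = bench$f_score,
                     rediscovery = redisc$rate))

  result <- structure(list(
    truth = truth, config = config,
    ctss = lapply(per_cond, `[[`, "ctss"),
    peaks = list(control = peaks_ctl, treated = peaks_trt),
    peak_audit = lapply(per_cond, `[[`, "peak_audit"),
    consensus = consensus, upregulated = upreg,
    benchmark = bench, rediscovery = redisc, stratified = strat,
    mappability = track, active_gtss = active,
    cryptic = cryptic, te_assignments = te_asn, enrichment = enrich,
    transcripts = models, proteome = proteome,
    antigens = antigens, antigen_summary = summary_tbl,
    manifest = manifest), class = "lrcage_run")

  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

config_md5 <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Write pipeline artifacts to a directory
#'
#' Emits TSV/GTF/FASTA/JSON artifacts for every stage plus the run
#' manifest. On failure, partially written files are removed.
#'
#' @param result An `lrcage_run` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(result, out_dir) {
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name) {
    p <- file.path(out_dir, name)
    fn(p)
    written <<- c(written, p)
  }
  tryCatch({
    emit(function(p) write_ctss(result$ctss$treated, p), "ctss_treated.tsv")
    emit(function(p) write_peaks(result$peaks$treated, p), "peaks_treated.tsv")
    emit(function(p) write_peaks(result$consensus, p), "consensus_peaks.tsv")
    emit(function(p) write_peaks(result$cryptic, p), "cryptic_tss.tsv")
    emit(function(p) fwrite(result$te_assignments, p, sep = "\t"),
         "te_assignments.tsv")
    if (!is.null(result$enrichment))
      emit(function(p) fwrite(result$enrichment, p, sep = "\t"),
           "te_enrichment.tsv")
    emit(function(p) write_models_gtf(result$transcripts, p),
         "transcripts.gtf")
    emit(function(p) fwrite(
      result$transcripts[, .(tx_id, gene_id, novelty_class, te_5prime_class,
                             context, tpm_control, tpm_treated,
                             drug_induced)], p, sep = "\t"),
      "transcripts.tsv")
    emit(function(p) write_proteome_fasta(result$proteome, p),
         "proteome.fa")
    emit(function(p) fwrite(
      result$antigens[, .(peptide_id, sequence, category, source_proteins,
                          detected_control, detected_treated, tpm_control,
                          tpm_treated, te_fraction, drug_induced_te)],
      p, sep = "\t"), "antigens.tsv")
    emit(function(p) write_mappability_bedgraph(result$mappability, p),
         "mappability.bedgraph")
    emit(function(p) jsonlite::write_json(
      list(precision = result$benchmark$precision,
           recall = result$benchmark$recall,
           f_score = result$benchmark$f_score,
           rediscovery = result$rediscovery$rate),
      p, auto_unbox = TRUE, digits = NA), "benchmark.json")
    emit(function(p) jsonlite::write_json(result$manifest, p,
                                          auto_unbox = TRUE, digits = NA),
         "manifest.json")
  }, error = function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  })
  invisible(out_dir)
}

#' @export
print.lrcage_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("lrcage pipeline run\n")
  cat(sprintf("  peaks (treated): %d; consensus: %d; up-regulated: %d\n",
              sc$peaks_treated, sc$consensus, sc$upregulated))
  cat(sprintf("  benchmark: precision %.3f, recall %.3f\n",
              x$benchmark$precision, x$benchmark$recall))
  cat(sprintf("  cryptic TSSs: %d; novel transcripts: %d; proteins: %d\n",
              sc$cryptic, sc$novel_transcripts, sc$proteins))
  cat(sprintf("  drug-induced TE antigens: %d\n",
              sc$drug_induced_te_antigens))
  invisible(x)
}
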