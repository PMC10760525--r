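#' Extract CTSSs (single-base 5'-end counts) from alignments
#'
#' For plus-strand reads the CTSS is the first aligned base; for
#' minus-strand reads, the last aligned base. Soft-clipped bases (such
#' as the unencoded cap G) never shift the CTSS. Counts aggregate reads
#' per (chrom, pos, strand). Alignments should already be filtered and
#' deduplicated.
#'
#' @param alignments Alignment table (see [filter_alignment()]).
#' @return A CTSS data.table: `chrom`, `pos` (0-based), `strand`,
#'   `count`, sorted by chrom, strand, pos.
#' @export
extract_ctss <- function(alignments) {
  aln <- as.data.table(alignments)
  if (nrow(aln) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), count = integer()))
  bad <- vapply(aln$blocks, function(b) is.null(b) || nrow(b) == 0L, logical(1))
  if (any(bad)) {
    warning(sprintf("skipping %d unaligned record(s)", sum(bad)))
    aln <- aln[!bad]
  }
  dt <- data.table(chrom = aln$chrom, pos = aln_end5(aln), strand = aln$strand)
  out <- dt[, .(count = .N), by = .(chrom, pos, strand)]
  setorder(out, chrom, strand, pos)
  out[]
}

## ---- paraclu ----------------------------------------------------------

## Density clustering of one sorted CTSS vector (positions pos, counts
## cnt): the maximal-scoring segments of score(S, d) = sum(counts) -
## d * span over all densities d > 0 (span = distance between first
## and last member site).
##
## Candidates are generated by recursive splitting at the weakest
## prefix/suffix density (the split density is the segment's exact
## max_density: removing a prefix and a suffix simultaneously is a
## mediant of the two single-sided trims, so single-sided trims attain
## the minimum). Each candidate's min_density - the largest d at which
## extending it increases the score, i.e. the d at which it merges
## upward - is then computed exactly as the best single-side
## boundary-anchored extension density (again, two-sided extensions
## are mediants). Candidates whose density interval (min_density,
## max_density) is empty are never maximal for any d and are dropped;
## the naive split recursion alone would report them.
paraclu_core <- function(pos, cnt) {
  n <- length(pos)
  out <- vector("list", 2L * n)
  n_out <- 0L
  emit <- function(i, j, dmax) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- c(i, j, dmax)
  }
  rec <- function(i, j) {
    if (i > j) return(invisible())
    if (i == j) { emit(i, j, Inf); return(invisible()) }
    cs <- cumsum(cnt[i:j])
    total <- cs[length(cs)]
    ## prefix density at split point m (right part starts at m):
    ## sum(cnt[i..m-1]) / (pos[m] - pos[i]), m in (i+1)..j
    m_right <- (i + 1L):j
    pref_d <- cs[m_right - i] / (pos[m_right] - pos[i])
    ## suffix density at split point s (left part ends at s):
    ## sum(cnt[s+1..j]) / (pos[j] - pos[s]), s in i..(j-1)
    s_left <- i:(j - 1L)
    suf_d <- (total - cs[s_left - i + 1L]) / (pos[j] - pos[s_left])
    pmin_i <- which.min(pref_d); smin_i <- which.min(suf_d)
    break_d <- min(pref_d[pmin_i], suf_d[smin_i])
    emit(i, j, break_d)
    if (pref_d[pmin_i] <= suf_d[smin_i]) {
      m <- m_right[pmin_i]
      rec(i, m - 1L); rec(m, j)
    } else {
      s <- s_left[smin_i]
      rec(i, s); rec(s + 1L, j)
    }
    invisible()
  }
  rec(1L, n)
  if (n_out == 0L) return(NULL)
  cand <- do.call(rbind, out[seq_len(n_out)])
  ## exact merge density per candidate
  cs <- cumsum(c(0, cnt))
  dmin <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    d_left <- if (i > 1L) {
      a <- 1L:(i - 1L)
      max((cs[i] - cs[a]) / (pos[i] - pos[a]))
    } else 0
    d_right <- if (j < n) {
      b <- (j + 1L):n
      max((cs[b + 1L] - cs[j + 1L]) / (pos[b] - pos[j]))
    } else 0
    max(d_left, d_right)
  }, numeric(1))
  keep <- cand[, 3L] > dmin
  if (!any(keep)) return(NULL)
  cbind(cand[keep, 1L], cand[keep, 2L], dmin[keep], cand[keep, 3L])
}

#' Cluster CTSSs into tag clusters with the paraclu algorithm
#'
#' Finds, per chromosome and strand, all maximal-scoring segments of
#' the CTSS profile under the score `sum(counts) - d * span` over all
#' densities `d > 0` (span = distance between the first and last member
#' CTSS). Each raw cluster carries `min_density` (largest density at
#' which it merges into its parent segment) and `max_density` (smallest
#' density at which it splits). Reported clusters must satisfy
#' `max_density / min_density >= min_stability`, have width at most
#' `max_length` bp, and total count at least `min_count`; overlapping
#' (nested) survivors are then reduced to a non-overlapping set,
#' preferring higher total count (ties: smaller width, then leftmost).
#'
#' @param ctss CTSS data.table from [extract_ctss()].
#' @param min_stability Minimum `max_density / min_density` ratio.
#' @param max_length Maximum cluster width in bp.
#' @param min_count Minimum total read count.
#' @param keep_singletons If `TRUE`, skip the non-overlap reduction and
#'   return the full filtered hierarchy (used by tests).
#' @return A tag cluster data.table: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `total_count`, `dominant_pos`,
#'   `dominant_count`, `min_density`, `max_density`.
#' @export
paraclu_cluster <- function(ctss, min_stability = 2, max_length = 500L,
                            min_count = 2L, keep_singletons = FALSE) {
  ctss <- as.data.table(ctss)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), total_count = integer(),
                      dominant_pos = integer(), dominant_count = integer(),
                      min_density = numeric(), max_density = numeric())
  if (nrow(ctss) == 0L) return(empty)
  assert_that(all(ctss$count >= 1L), "CTSS counts must be positive")
  setorder(ctss, chrom, strand, pos)
  assert_that(!anyDuplicated(ctss[, .(chrom, strand, pos)]),
              "duplicate CTSS positions within a chrom/strand")
  groups <- split(ctss, by = c("chrom", "strand"), drop = TRUE)
  res <- lapply(groups, function(g) {
    raw <- paraclu_core(g$pos, g$count)
    if (is.null(raw)) return(NULL)
    i <- raw[, 1L]; j <- raw[, 2L]
    cs <- cumsum(c(0L, g$count))
    tot <- cs[j + 1L] - cs[i]
    dom <- mapply(function(a, b) {
      k <- a + which.max(g$count[a:b]) - 1L
      c(g$pos[k], g$count[k])
    }, i, j)
    data.table(chrom = g$chrom[1L], start = g$pos[i], end = g$pos[j] + 1L,
               strand = g$strand[1L], total_count = as.integer(tot),
               dominant_pos = as.integer(dom[1L, ]),
               dominant_count = as.integer(dom[2L, ]),
               min_density = raw[, 3L], max_density = raw[, 4L])
  })
  cl <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(cl) == 0L) return(empty)
  cl <- cl[max_density / pmax(min_density, .Machine$double.xmin) >= min_stability &
             (end - start) <= max_length & total_count >= min_count]
  if (nrow(cl) == 0L) return(empty)
  if (!keep_singletons) cl <- reduce_nonoverlapping(cl)
  setorder(cl, chrom, strand, start)
  cl[]
}

## Greedy reduction to a non-overlapping set per chrom/strand,
## preferring higher total_count, then smaller width, then leftmost.
reduce_nonoverlapping <- function(cl) {
  cl <- copy(cl)
  cl[, .w := end - start]
  setorder(cl, -total_count, .w, chrom, strand, start)
  kept <- logical(nrow(cl))
  for (grp in split(seq_len(nrow(cl)),
                    paste(cl$chrom, cl$strand))) {
    taken <- NULL
    for (r in grp) {
      s <- cl$start[r]; e <- cl$end[r]
      if (is.null(taken) || !any(s < taken[, 2L] & e > taken[, 1L])) {
        kept[r] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
  }
  out <- cl[kept]
  out[, .w := NULL]
  out[]
}

## ---- cap-signal filter ------------------------------------------------

#' Filter tag clusters by the template-switching cap signature
#'
#' During template switching, reverse transcriptase adds a non-templated
#' guanosine opposite the 5' cap, so reads from genuine capped 5' ends
#' tend to carry an extra G immediately 5' of their aligned start that
#' does not match the genome. For each cluster this computes the
#' fraction of member reads with such an unencoded G (the base adjacent
#' to the aligned start within the 5' soft-clip is `G`, and the genomic
#' base just upstream of the aligned start differs, strand-aware), and
#' retains clusters whose fraction is at least `cutoff`. The fraction is
#' recorded on every cluster (survivor or casualty) in the audit output.
#'
#' @param clusters Tag cluster table from [paraclu_cluster()].
#' @param alignments Alignment table of the reads the clusters were
#'   built from.
#' @param genome Named character vector or `DNAStringSet`.
#' @param cutoff Minimum unencoded-G fraction (default 0.35).
#' @return List with `kept` (clusters with a `cap_g_fraction` column)
#'   and `audit` (all clusters with fractions and decisions).
#' @export
cap_signal_filter <- function(clusters, alignments, genome, cutoff = 0.35) {
  cl <- as.data.table(clusters)
  if (nrow(cl) == 0L)
    return(list(kept = cl, audit = cl))
  aln <- as.data.table(alignments)
  seqs <- genome_as_character(genome)
  pos <- aln_end5(aln)
  last5 <- substr(aln$clip5_seq, nchar(aln$clip5_seq), nchar(aln$clip5_seq))
  up_pos <- ifelse(aln$strand == "+", pos - 1L, pos + 1L)
  chrom_len <- nchar(seqs)[aln$chrom]
  valid <- up_pos >= 0L & up_pos < chrom_len
  gbase <- rep(NA_character_, nrow(aln))
  gbase[valid] <- substr(seqs[aln$chrom[valid]], up_pos[valid] + 1L,
                         up_pos[valid] + 1L)
  ## the read-orientation G corresponds to genomic G (+) or C (-)
  match_base <- ifelse(aln$strand == "+", "G", "C")
  has_g <- aln$clip5 >= 1L & last5 == "G" &
    (!valid | gbase != match_base)
  reads <- data.table(chrom = aln$chrom, strand = aln$strand, pos = pos,
                      has_g = has_g)
  cl <- copy(cl)
  cl[, cap_g_fraction := {
    frac <- numeric(.N)
    for (r in seq_len(.N)) {
      m <- reads[chrom == cl$chrom[r] & strand == cl$strand[r] &
                   pos >= cl$start[r] & pos < cl$end[r]]
      if (nrow(m) == 0L)
        stop("cluster with zero supporting reads: inconsistent inputs",
             call. = FALSE)
      frac[r] <- mean(m$has_g)
    }
    frac
  }]
  list(kept = cl[cap_g_fraction >= cutoff],
       audit = cl[, .(chrom, start, end, strand, cap_g_fraction,
                      decision = ifelse(cap_g_fraction >= cutoff,
                                        "keep", "discard"))])
}

## ---- annotation, consensus, differential ------------------------------

#' Assign a genomic category to each peak
#'
#' The dominant CTSS position of each peak is tested against annotation
#' features in fixed priority order: promoter (strand-aware window
#' around annotated TSSs), 5' UTR, first exon, 3' UTR, other exons,
#' intron, and intergenic otherwise.
#'
#' @param peaks Tag cluster table with `dominant_pos`.
#' @param annotation An [tx_annotation()] object.
#' @return The peaks table with a `category` column.
#' @export
annotate_peaks <- function(peaks, annotation) {
  stopifnot(inherits(annotation, "lrcage_annotation"))
  pk <- copy(as.data.table(peaks))
  if (nrow(pk) == 0L) { pk[, category := character(0)]; return(pk[]) }
  pts <- pk[, .(chrom, pos = dominant_pos, strand)]
  category <- rep("intergenic", nrow(pk))
  order_feats <- c("promoter", "utr5", "first_exon", "utr3", "other_exon",
                   "intron")
  unassigned <- rep(TRUE, nrow(pk))
  for (f in order_feats) {
    hit <- point_in_intervals(pts, annotation$features[[f]],
                              stranded = (f == "promoter"))
    category[unassigned & hit] <- f
    unassigned <- unassigned & !hit
  }
  pk[, category := category]
  pk[]
}

#' Merge per-library peak sets into strand-aware consensus peaks
#'
#' Takes the union of overlapping same-strand clusters across libraries
#' and fills per-library counts by summing member CTSS counts inside
#' each consensus interval; per-library counts are also normalised to
#' counts per million.
#'
#' @param peak_sets Named list of tag cluster tables (one per library).
#' @param ctss_sets Optional named list of CTSS tables matching
#'   `peak_sets`; when given, library counts sum CTSS counts, otherwise
#'   they sum member cluster totals.
#' @return Consensus peak table with `count_<library>` and
#'   `cpm_<library>` columns.
#' @export
merge_consensus_peaks <- function(peak_sets, ctss_sets = NULL) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1L)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("lib", seq_along(peak_sets))
  all_pk <- rbindlist(lapply(peak_sets, function(p)
    as.data.table(p)[, .(chrom, start, end, strand)]), use.names = TRUE)
  if (nrow(all_pk) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  gr <- GenomicRanges::reduce(gr0(all_pk$chrom, all_pk$start, all_pk$end,
                                  all_pk$strand))
  cons <- dt0(gr)
  setDT(cons)
  for (lib in names(peak_sets)) {
    src <- if (!is.null(ctss_sets)) {
      cts <- as.data.table(ctss_sets[[lib]])
      cts[, .(chrom, pos, strand, n = count)]
    } else {
      pk <- as.data.table(peak_sets[[lib]])
      pk[, .(chrom, pos = dominant_pos, strand, n = total_count)]
    }
    cnt <- integer(nrow(cons))
    if (nrow(src)) {
      q <- gr0(src$chrom, src$pos, src$pos + 1L, src$strand)
      hits <- GenomicRanges::findOverlaps(q, gr)
      agg <- tapply(src$n[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
      cnt[as.integer(names(agg))] <- as.integer(agg)
    }
    cons[[paste0("count_", lib)]] <- cnt
    tot <- sum(cnt)
    cons[[paste0("cpm_", lib)]] <- if (tot > 0) cnt / tot * 1e6 else 0
  }
  setorder(cons, chrom, strand, start)
  cons[]
}

#' Flag up-regulated peaks by normalised fold change
#'
#' Computes `fold = ((treated + pseudocount) / treated_total) /
#' ((control + pseudocount) / control_total)` per peak and flags peaks
#' with `fold >= min_fold` (default fourfold). This is the count-ratio
#' rule only; dispersion-based significance testing is intentionally
#' out of scope.
#'
#' @param consensus Consensus peak table.
#' @param treated_counts,control_counts Integer vectors aligned with
#'   `consensus` rows.
#' @param min_fold Minimum fold change.
#' @param pseudocount Added to both counts before normalisation.
#' @return `consensus` with `fold` and `upregulated` columns.
#' @export
call_upregulated_peaks <- function(consensus, treated_counts, control_counts,
                                   min_fold = 4, pseudocount = 1) {
  stopifnot(length(treated_counts) == nrow(consensus),
            length(control_counts) == nrow(consensus))
  assert_that(all(treated_counts >= 0) && all(control_counts >= 0),
              "counts must be nonnegative")
  t_tot <- sum(treated_counts); c_tot <- sum(control_counts)
  assert_that(t_tot > 0 && c_tot > 0, "zero library totals")
  out <- copy(as.data.table(consensus))
  out[, fold := ((treated_counts + pseudocount) / t_tot) /
        ((control_counts + pseudocount) / c_tot)]
  out[, upregulated := fold >= min_fold]
  out[]
}
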