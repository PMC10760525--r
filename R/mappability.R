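#' Compute a k-mer uniqueness (mappability) track
#'
#' A k-mer is unique when its canonical form (the lexicographic minimum
#' of the k-mer and its reverse complement) occurs exactly once across
#' all chromosomes; counting the canonical form counts both strands at
#' once, so a palindromic k-mer occurring at one position is still
#' unique. The score of a genomic position is the fraction of the at
#' most k k-mers covering it that are unique; within k-1 of a
#' chromosome end, only the k-mers that exist are averaged.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param k K-mer length (default 50, >= 2).
#' @return An object of class `mappability_track`: list with `k` and
#'   `scores`, a named list of per-chromosome numeric vectors in [0,1]
#'   (index 1 = position 0).
#' @export
compute_mappability <- function(genome, k = 50L) {
  seqs <- genome_as_character(genome)
  assert_count(k, "k", min = 2L)
  assert_that(length(seqs) > 0L && all(nzchar(seqs)), "genome is empty")
  lens <- nchar(seqs)
  assert_that(any(lens >= k), "k is longer than every chromosome")
  kmers <- list()
  for (ch in names(seqs)) {
    L <- lens[[ch]]
    if (L < k) { kmers[[ch]] <- character(0); next }
    starts <- seq_len(L - k + 1L)
    kmers[[ch]] <- substring(seqs[[ch]], starts, starts + k - 1L)
  }
  all_k <- unlist(kmers, use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_k)))
  canon <- pmin(all_k, rc)
  tab <- table(canon)
  uniq_flag <- as.integer(tab[canon] == 1L)
  scores <- list()
  off <- 0L
  for (ch in names(seqs)) {
    L <- lens[[ch]]
    nk <- length(kmers[[ch]])
    if (nk == 0L) { scores[[ch]] <- rep(NA_real_, L); next }
    u <- uniq_flag[(off + 1L):(off + nk)]
    off <- off + nk
    cs <- c(0L, cumsum(u))
    p <- seq_len(L)                       # 1-based position
    lo <- pmax(1L, p - k + 1L)            # first covering k-mer start
    hi <- pmin(p, nk)                     # last covering k-mer start
    scores[[ch]] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  structure(list(k = as.integer(k), scores = scores),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("mappability track: k=%d, %d chromosome(s)\n",
              x$k, length(x$scores)))
  invisible(x)
}

#' Mean mappability of a region, with low-mappability flag
#'
#' @param track A [compute_mappability()] track.
#' @param chrom Chromosome name.
#' @param start,end Region, 0-based half-open.
#' @param low_threshold Regions with mean score `<=` this value are
#'   flagged low-mappability (default 0.5; the bound is inclusive).
#' @param edge `"error"` to reject regions extending past the
#'   chromosome, `"clamp"` to truncate them.
#' @return List with `mean_score` and `is_low`.
#' @export
region_score <- function(track, chrom, start, end, low_threshold = 0.5,
                         edge = c("error", "clamp")) {
  stopifnot(inherits(track, "mappability_track"))
  edge <- match.arg(edge)
  assert_that(chrom %in% names(track$scores), "unknown chromosome")
  v <- track$scores[[chrom]]
  assert_that(end > start, "empty interval")
  if (start < 0L || end > length(v)) {
    if (edge == "error") stop("region outside chromosome bounds",
                              call. = FALSE)
    start <- max(0L, start); end <- min(length(v), end)
    assert_that(end > start, "region entirely outside chromosome")
  }
  m <- mean(v[(start + 1L):end], na.rm = TRUE)
  list(mean_score = m, is_low = m <= low_threshold)
}

#' Score TSS positions by surrounding mappability
#'
#' Convenience wrapper: mean track score in a +/- `flank` window around
#' each position (clamped at chromosome ends).
#'
#' @param track A mappability track.
#' @param tss data.table with `chrom`, `pos`.
#' @param flank Window half-width in bp.
#' @param low_threshold Passed to [region_score()].
#' @return Numeric vector of mean scores.
#' @export
tss_mappability <- function(track, tss, flank = 100L, low_threshold = 0.5) {
  vapply(seq_len(nrow(tss)), function(i)
    region_score(track, tss$chrom[i], tss$pos[i] - flank,
                 tss$pos[i] + flank + 1L, low_threshold,
                 edge = "clamp")$mean_score,
    numeric(1))
}

#' Export a mappability track as bedGraph
#'
#' @param track A mappability track.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mappability_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=mappability_k%d", track$k), con)
  for (ch in names(track$scores)) {
    v <- round(track$scores[[ch]], 6)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values)
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}
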