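#' @import data.table
#' @importFrom methods is
#' @importFrom stats runif setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## All genomic coordinates inside the package are 0-based half-open.
## GRanges (1-based closed) is used only at overlap/IO boundaries via
## the two converters below.

#' Convert 0-based half-open intervals to a GRanges
#'
#' @param chrom,start,end,strand Vectors describing intervals in the
#'   package-internal 0-based half-open convention.
#' @return A [GenomicRanges::GRanges] (1-based closed).
#' @keywords internal
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand
  )
}

#' Convert a GRanges back to a 0-based half-open data.table
#' @keywords internal
dt0 <- function(gr) {
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min,
              sprintf("'%s' must be a single integer >= %d", name, min))
}

#' Run code with a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so fixture generation never perturbs user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a character DNA string
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## exons: integer matrix with columns start, end (0-based half-open),
## rows sorted by genomic position.
exon_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L]), , drop = FALSE]
}

exon_widths <- function(exons) exons[, 2L] - exons[, 1L]

#' Genomic 5'-end (TSS) of an exon chain, strand aware
#' @keywords internal
tss_of <- function(exons, strand) {
  if (strand == "+") exons[1L, 1L] else exons[nrow(exons), 2L] - 1L
}

#' Map a transcript-coordinate interval to genomic blocks
#'
#' @param exons Exon matrix (0-based half-open, genomically sorted).
#' @param strand Transcript strand.
#' @param tx_start,tx_end Interval in transcript coordinates
#'   (0-based half-open, 0 = the TSS-proximal base).
#' @return Exon-style matrix of genomic blocks covered by the interval.
#' @keywords internal
tx_to_genome_blocks <- function(exons, strand, tx_start, tx_end) {
  w <- exon_widths(exons)
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  offs <- cumsum(c(0L, w[ord]))[seq_along(ord)]
  blocks <- list()
  for (i in seq_along(ord)) {
    e <- ord[i]
    lo <- max(tx_start, offs[i]); hi <- min(tx_end, offs[i] + w[e])
    if (lo >= hi) next
    if (strand == "+") {
      gs <- exons[e, 1L] + (lo - offs[i]); ge <- exons[e, 1L] + (hi - offs[i])
    } else {
      ge <- exons[e, 2L] - (lo - offs[i]); gs <- exons[e, 2L] - (hi - offs[i])
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  exon_matrix(m[, 1L], m[, 2L])
}

#' Spliced transcript sequence from a genome
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param chrom,exons,strand Transcript location (0-based half-open exons).
#' @return Character scalar, 5' to 3' in transcript orientation.
#' @export
transcript_sequence <- function(genome, chrom, exons, strand) {
  seqs <- genome_as_character(genome)
  s <- seqs[[chrom]]
  pieces <- apply(exons, 1L, function(b) substr(s, b[1L] + 1L, b[2L]))
  out <- paste(pieces, collapse = "")
  if (strand == "-") out <- revcomp(out)
  out
}

genome_as_character <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    stopifnot(is.character(genome), !is.null(names(genome)))
    genome
  }
}

genome_base <- function(genome, chrom, pos0) {
  s <- genome_as_character(genome)[[chrom]]
  substr(s, pos0 + 1L, pos0 + 1L)
}
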