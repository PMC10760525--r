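## Independent brute-force oracles used across the suite. These never
## share code paths with the implementation they check.

## All maximal-scoring segments of a CTSS profile, by exhaustive
## enumeration over every segment pair: a segment is maximal for some
## density d iff the open interval (d_low, d_high) is nonempty, where
## d_low is the best score gain per extra span over all strict
## supersets and d_high the least score loss per removed span over all
## strict subsegments.
brute_paraclu <- function(pos, cnt) {
  n <- length(pos)
  segs <- list()
  for (a in 1:n) for (b in a:n)
    segs[[length(segs) + 1L]] <- c(a, b, sum(cnt[a:b]), pos[b] - pos[a])
  S <- do.call(rbind, segs)
  out <- list()
  for (i in seq_len(nrow(S))) {
    a <- S[i, 1]; b <- S[i, 2]; C <- S[i, 3]; sp <- S[i, 4]
    sup <- S[, 1] <= a & S[, 2] >= b & !(S[, 1] == a & S[, 2] == b)
    sub <- S[, 1] >= a & S[, 2] <= b & !(S[, 1] == a & S[, 2] == b)
    d_low <- if (any(sup)) max((S[sup, 3] - C) / (S[sup, 4] - sp)) else 0
    d_high <- if (any(sub)) min((C - S[sub, 3]) / (sp - S[sub, 4])) else Inf
    if (d_high > d_low)
      out[[length(out) + 1L]] <- data.frame(
        start = pos[a], end = pos[b] + 1L, total = C,
        dmin = d_low, dmax = d_high)
  }
  o <- do.call(rbind, out)
  o[order(o$start, o$end), , drop = FALSE]
}

## Run the packaged paraclu on a raw profile and return the unfiltered
## hierarchy in the oracle's format.
paraclu_raw <- function(pos, cnt) {
  raw <- lrcage:::paraclu_core(pos, cnt)
  o <- data.frame(start = pos[raw[, 1]], end = pos[raw[, 2]] + 1L,
                  total = mapply(function(i, j) sum(cnt[i:j]),
                                 raw[, 1], raw[, 2]),
                  dmin = raw[, 3], dmax = raw[, 4])
  o[order(o$start, o$end), , drop = FALSE]
}

expect_paraclu_matches_oracle <- function(pos, cnt) {
  bf <- brute_paraclu(pos, cnt)
  imp <- paraclu_raw(pos, cnt)
  expect_equal(imp$start, bf$start)
  expect_equal(imp$end, bf$end)
  expect_equal(imp$total, bf$total)
  expect_equal(imp$dmin, bf$dmin, tolerance = 1e-12)
  expect_equal(imp$dmax, bf$dmax, tolerance = 1e-12)
}

## Per-position k-mer uniqueness by direct occurrence counting with
## Biostrings pattern matching (both strands; palindromes counted once).
brute_mappability <- function(genome, k) {
  seqs <- Biostrings::DNAStringSet(genome)
  out <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    starts <- seq_len(L - k + 1L)
    km <- Biostrings::DNAStringSet(
      substring(genome[[ch]], starts, starts + k - 1L))
    pd <- Biostrings::PDict(km)
    fwd <- rowSums(Biostrings::vcountPDict(pd, seqs))
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(km))
    rev_ <- rowSums(Biostrings::vcountPDict(pd_rc, seqs))
    is_pal <- as.character(km) ==
      as.character(Biostrings::reverseComplement(km))
    occ <- ifelse(is_pal, fwd, fwd + rev_)
    u <- as.integer(occ == 1L)
    cs <- c(0L, cumsum(u))
    p <- seq_len(L)
    lo <- pmax(1L, p - k + 1L)
    hi <- pmin(p, length(u))
    out[[ch]] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

## Longest ATG-initiated, stop-terminated ORF by explicit codon walk.
oracle_codon_table <- Biostrings::GENETIC_CODE

oracle_longest_orf <- function(seq, min_aa = 100L) {
  n <- nchar(seq)
  best <- NULL
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atg[1] == -1) return(NULL)
  for (a in atg) {
    p <- a; n_aa <- 0L; prot <- character(0); terminated <- FALSE
    while (p + 2L <= n) {
      aa <- oracle_codon_table[[substr(seq, p, p + 2L)]]
      if (aa == "*") { terminated <- TRUE; break }
      prot <- c(prot, aa); n_aa <- n_aa + 1L; p <- p + 3L
    }
    if (!terminated || n_aa < min_aa) next
    if (is.null(best) || n_aa > best$n_aa ||
        (n_aa == best$n_aa && (a - 1L) < best$start))
      best <- list(start = a - 1L, end = a - 1L + 3L * (n_aa + 1L),
                   protein = paste(prot, collapse = ""), n_aa = n_aa)
  }
  best
}

## Stop-free stretches of all three forward frames by codon walk.
oracle_three_frame <- function(seq, min_aa = 25L) {
  peps <- character(0)
  for (f in 0:2) {
    p <- f + 1L; cur <- character(0)
    while (p + 2L <= nchar(seq)) {
      aa <- oracle_codon_table[[substr(seq, p, p + 2L)]]
      if (aa == "*") {
        if (length(cur) >= min_aa)
          peps <- c(peps, paste(cur, collapse = ""))
        cur <- character(0)
      } else cur <- c(cur, aa)
      p <- p + 3L
    }
    if (length(cur) >= min_aa) peps <- c(peps, paste(cur, collapse = ""))
  }
  sort(peps)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
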