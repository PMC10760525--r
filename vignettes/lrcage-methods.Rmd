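---
title: "Methods: long-read CAGE TSS calling, TE promoter discovery, and antigen classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read CAGE TSS calling, TE promoter discovery, and antigen classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcage)
```

# Scope and model

`lrcage` analyses Cap Analysis of Gene Expression (CAGE) data produced
with long-read (LRCAGE: poly-dT primed, full length; LRhex: random
hexamer primed, 5' portions) or short-read (nanoCAGE) protocols. The
analysis chain is: protocol-aware read trimming, alignment filtering
and UMI deduplication, CTSS extraction, paraclu tag clustering,
cap-signal filtering, benchmarking against annotation-derived active
TSSs, cryptic TSS and transposable-element (TE) analysis, transcript
model filtering and novelty classification, ORF prediction with an NMD
filter, custom proteome construction, and immunopeptidome peptide
classification. All internal coordinates are 0-based half-open; SAM,
GTF, and BED interfaces follow their own standards.

# Read preprocessing

Template-switching chemistry leaves a fixed prefix on every read:
linker, an 8-nt unique molecular identifier (UMI), and a `TATAGGG`
spacer. The oligo sequence itself is not standardised, so the trimmer
and the read simulator share one configurable layout
(`tso_linker`, `umi_length`, `tso_spacer` in `pipeline_config()`).
Trimming removes the prefix, captures the UMI, removes up to 15
terminal A's (LRCAGE only), and keeps reads of at least 250 bp —
the full-length nonchimeric (FLNC) criterion. nanoCAGE reads are
~75 bp fragments, so the FLNC floor cannot apply; they get a 20-bp
floor and, because the protocol statement is silent on the matter, no
soft-clip filter. Aligned long reads are discarded when secondary,
supplementary, multimapping, or soft-clipped beyond 3 bases at either
end (LRCAGE) or 3 at the 5' / 20 at the 3' end (LRhex); clip
orientation is read-strand relative. Deduplication keys on both end
coordinates plus the exact UMI — the conservative reading of
"coordinates and UMIs" — keeping the highest-quality, then
lexicographically smallest, read id, so output is independent of input
order and the operation is idempotent.

# CTSS extraction and paraclu clustering

A CTSS is the strand-aware first aligned base of a read; soft-clipped
bases (including the unencoded cap G) never shift it. Tag clusters are
the maximal-scoring segments of the CTSS profile under
`score(S, d) = sum(counts) - d * span` over all densities `d > 0`,
with span the distance between the first and last member site. Each
cluster carries the density interval on which it is maximal:
`min_density`, the largest `d` at which extending the segment still
increases its score (0 for the root segment), and `max_density`, the
smallest `d` at which trimming does.

Candidates are generated by recursively splitting at the weakest
prefix/suffix density. The split density is the exact `max_density`:
removing a prefix and a suffix together is a count/span mediant of the
two single-sided trims, so a single-sided trim always attains the
minimum. The merge density is then computed exactly per candidate as
the best single-sided boundary-anchored extension density (the same
mediant argument applies to two-sided extensions). The second step
matters: the plain split recursion, run with inherited break densities
alone, reports segments whose density interval is empty — segments
that are maximal for no `d` at all — whenever a weak sibling is
detached before the stronger sibling's merge density is reached. The
test suite checks exact equality, including both densities, against an
independent enumeration over all O(n^2) segment pairs on hundreds of
random profiles.

Reported clusters must satisfy `max_density / min_density >= 2`
(stability), width at most 500 bp, and at least 2 supporting reads;
nested survivors are reduced to a non-overlapping set preferring
higher counts, then smaller width, then leftmost — these four
parameters follow the conventions of the established paraclu callers
and are all configurable, since the source protocol names the
algorithm but not its settings.

# Cap-signal filtering

Reverse transcriptase adds a non-templated guanosine opposite the 5'
cap, so reads that truly start at a cap tend to carry an extra G
immediately 5' of their aligned start that does not match the genome.
The cap statistic of a cluster is the fraction of member reads with
such an unencoded G (soft-clipped base adjacent to the aligned start
is `G` and the strand-aware upstream genomic base differs). Clusters
with a fraction below 0.35 are removed; the fraction is recorded on
survivors and casualties alike. The exact statistic of the tool the
cutoff originates from is not published; the unencoded-G fraction is
the template-switching cap signature that cutoff is naturally read
against, and the cutoff is configurable.

# Benchmarking

Active annotated TSSs are transcripts that are protein-coding, 0.3–1
kbp long (the printed range is the literal default; `(300, Inf)` is a
documented alternative since length-stratified analyses of much longer
transcripts exist), and expressed at >= 1 TPM by both of two
quantifier tables (0.1 TPM for the relaxed set). Identical TSS
positions collapse to one record keeping the maximum TPM. A TSS is
detected when a same-strand peak expanded by the 200-bp tolerance
contains it; recall is the detected fraction, precision the fraction
of peaks matching at least one active TSS. The source text defines
precision as the fraction of peaks that did *not* overlap — read here
as a typo for the standard quantity its own figures use. Rediscovery
asks instead for a single same-strand CTSS position within ±200 bp
carrying at least 2 reads. Stratified recall (by TPM, mappability
class, or transcript length) reports empty strata as `NA`, and its
size-weighted mean reproduces overall recall by construction.

# Mappability

The published analysis stratifies TSSs by a precomputed mappability
track of unstated window size; this package instead defines a
self-contained multi-read k-mer uniqueness score so that tests and
pipelines need no external download. A k-mer is unique when its
canonical form (minimum of the k-mer and its reverse complement)
occurs exactly once genome-wide — counting canonical forms counts
both strands at once and counts palindromes once. A position's score
is the fraction of its covering k-mers that are unique; near
chromosome ends only existing k-mers are averaged. `k = 50`
approximates short-read regimes; regions are scored as the mean over
±100 bp around a TSS, and means at or below 0.5 are "low
mappability" (the bound is inclusive). Both `k` and the window are
configurable.

# Cryptic TSSs, TE enrichment, and TE age

A cryptic TSS is a peak whose dominant CTSS lies at least 200 bp from
every same-strand annotated TSS and whose interval overlaps no
annotated exon on either strand (strand-agnostic exon exclusion is
the conservative reading and guards against incomplete reverse
transcription). Each cryptic peak is assigned to the smallest TE
element containing its dominant position — containment, not interval
overlap, so each cryptic TSS gets one TE — with sense/antisense
orientation relative to the TE. Subfamily enrichment uses the
observed/expected element-count ratio `(o_s/O) / (n_s/N)`; the score
formula is not printed in the source, and this is the simplest
interpretation consistent with its element-count side conditions
(score >= 1.5, >= 100 catalog elements, >= 5 overlapping elements). A
base-pair-weighted variant can be obtained by grouping on any catalog
column. TE age is divergence (substitutions over genomic length minus
insertions) divided by the neutral rate 2.2e-9 per site per year.

# Transcript models and proteome

Transcript models keep only those whose TSS falls within a same-strand
peak expanded by 50 bp (slack 0 reproduces strict containment; the
source states only "supported by the merged peaks"). Novelty is a
splice-chain comparison in the style of long-read isoform
classifiers: `known` (exact junction-chain match), `ISM` (contiguous
sub-chain), `NIC` (all junctions known, chain novel), `NNC` (novel
junction within a same-strand gene), `antisense`, `intergenic`, and
`genomic` (mono-exonic inside a gene without junction evidence). The
classifier is reimplemented rather than wrapped: the external tool's
database machinery and read-collapsing are out of scope here.
Quantification is full-length read counting (TPM without length
normalisation). LTR-initiated models get a context with precedence
proviral > genic > unannotated. A transcript is drug-induced at
>= 1 TPM treated and exactly 0 TPM control.

Proteins are the longest ATG-initiated, stop-terminated ORF of at
least 100 aa per transcript (ties to the 5'-most start; ORFs running
off the 3' end are excluded, configurably). The NMD filter is the
canonical 50-nt rule — drop when the stop codon starts more than
50 nt upstream of the last exon-exon junction; mono-exonic
transcripts are kept. Proviral HERV transcripts are additionally
expanded by three-frame translation into stop-free stretches of at
least 25 aa with no start requirement. Novel proteins are classified
against same-gene reference proteins with a 10-aa minimum shared
block: annotated, truncated, chimeric, chimeric_truncated,
novel_internal, and out_of_frame / unannotated_coding (by CDS
overlap); the published classification scheme is qualitative, and
these substring/terminal-block rules are this package's
operationalisation, with every threshold configurable. The custom
proteome unions reference and novel proteins, drops exact duplicates
of reference sequences, and numbers novel entries `<gene>_NP_<n>`
deterministically.

# Antigen classification

A peptide is canonical when it occurs verbatim in the reference
proteome — exact substring search, which is equivalent to 100%-identity
alignment for short peptides and fully reproducible. Isoleucine and
leucine are *not* equated by default (a switch exists). Noncanonical
peptides are TE antigens only when every custom-proteome source places
every occurrence within or overlapping a TE-coded residue range — the
most conservative reading when sources disagree. Per-peptide
expression sums the TPM of all encoding transcripts (the attribution
rule when a peptide maps to several transcripts is unstated; summing
is assumed). A drug-induced TE antigen is detected under treatment
only, with more than 90% of its expression from TE transcripts and a
more than 10-fold expression change; a control TPM of 0 gives
infinite fold and passes. Both bounds are strict.

# The synthetic fixture

The generator emulates the study design at desk scale: a two-
chromosome 120-kb genome, 20 annotated multi-exon protein-coding
genes, a 24-element TE catalog, 5 cryptic TE promoters (one LTR12C
inside a proviral HERV interval and expressed only under treatment —
the drug-induced unit; one LTR12E in a host gene's first intron,
expressed in both conditions; the rest intergenic), and one 2-kb
segment copied verbatim to create a low-mappability region. Genes get
an A-free 5' UTR (no ATG can precede the planted CDS in frame), a
random CDS verified to be the transcript's longest ORF, and a stop
codon inside the last exon (NMD-safe). The base immediately upstream
of every TSS is forced to a non-G so an unencoded cap G can never be
absorbed into the alignment. Expression is weight-based: TPM is exact
by construction, and the two conditions mimic a DMSO-like control and
an epigenetically treated state in which TE units switch on. Three
peptides are planted: one copied from an annotated protein (canonical),
one from the TE-coded residues of the drug-induced unit (detected under
treatment only), and one from the non-TE 3' exon of the constitutive
cryptic unit.

Reads carry the shared TSO layout, per-molecule UMIs drawn without
replacement (so deduplication must recover exactly one read per
molecule), an unencoded G on 90% of capped molecules, and 15-A tails
(LRCAGE). Noise injects PCR duplicates, 4-base excess soft-clips, and
5'-truncated uncapped molecules at a configurable rate. The simulator
does not model sequencing errors, quality scores, or chimeras, and TE
"sequences" are annotations over random background rather than real
consensus sequences — so passing tests demonstrate the correctness of
the rules and algorithms, not robustness to base-level noise or
homology-driven mis-assignment on real genomes.

# Numerical choices and problem sizes

Determinism: every stochastic step runs under an explicitly derived
seed and restores the caller's RNG state; rerunning a pipeline with
one config is bit-identical, and the run manifest (config hash, stage
counts) contains no timestamps. Tie-breaks are always lexicographic or
leftmost. The test suite sizes are chosen to exercise the mathematics
while staying desk-scale: paraclu oracle equivalence on 200+ random
profiles of up to 30 sites, mappability oracle equality on a 50-kb
two-chromosome genome for k in {21, 50}, ORF/translation oracles on
1000 random 1–3-kb sequences, and the full pipeline on the standard
fixture above.

# Known limitations

The paraclu implementation recomputes merge densities in O(n) per
candidate (O(n^2) worst case per chromosome/strand profile), which is
ample for clustered CAGE signal but not tuned for pathological
genome-wide profiles. Mappability holds all canonical k-mers in
memory, appropriate up to bacterial-genome scale, not for a full human
genome. The protein subclass boundaries and the enrichment score are
operationalisations of qualitative descriptions; both are configurable
and documented above. Statistical testing of differential peaks
(dispersion modelling, multiple-testing correction) is deliberately
out of scope: only the normalised fourfold count-ratio rule is
implemented.

```{r example}
cfg <- pipeline_config()
run <- run_pipeline(cfg)
run$benchmark$recall
run$antigen_summary
```
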