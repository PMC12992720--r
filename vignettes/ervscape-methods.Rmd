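---
title: "Methods: silencing potential, LTR dating, ORF integrity and recombination calling"
author: "ervscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: silencing potential, LTR dating, ORF integrity and recombination calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscape)
```

# Scope and data model

`ervscape` analyses the evolutionary state of LTR retrotransposons --
in particular insect endogenous retroviruses (iERVs, errantiviruses),
gypsy-clade elements that ancestrally carry an F-type envelope gene
(*env-F*) conferring infectivity. Four questions drive the design:

1. How much of a TE consensus can a piRNA cluster silence
   (**silencing potential**)?
2. How old is a given genomic insertion (**LTR dating**)?
3. Is an insertion still coding-competent, and did it lose *env-F*
   (**ORF integrity**)?
4. Did an insertion arise by template switching between co-packaged
   variant genomes (**recombination calling**)?

The central containers are S4 classes over Biostrings/GenomicRanges
types: a `ConsensusElement` holds a consensus sequence plus a feature
`GRanges` (LTR5, UTR5, GAG, POL, ENVF, UTR3, LTR3); an
`InsertionRecord` holds one extracted, element-oriented genomic copy.
Feature coordinates are 1-based closed in memory (the Bioconductor
convention); the on-disk annotation table and all BED output are
0-based half-open, converted at the I/O boundary. Sequences are
normalized on input (uppercase, U to T); IUPAC ambiguity codes other
than N are rejected rather than silently converted, because exact
k-mer matching downstream must be unambiguous.

# Silencing potential

A cluster sequence is decomposed into all distinct k-mers, shifted by
1 nt (default `k = 25`, the typical piRNA length whose footprint the
statistic mimics). A consensus position is *covered* when it lies in at
least one k-length consensus window whose reverse complement occurs in
the cluster (antisense orientation); the silencing potential is the
covered fraction of the consensus. Matching is binary and set-based:
k-mer multiplicity is deliberately ignored, since one perfect
piRNA-target match is as good as ten for the presence/absence question
the statistic answers.

Orientation matters biologically: only antisense cluster content yields
TE-complementary piRNAs. Uni-strand clusters are indexed in their
transcribed orientation only; dual-strand clusters are indexed on both
strands (`bothStrands = TRUE`), as both genomic strands are
transcribed. Because k is odd, no window can be its own reverse
complement, so a sense-embedded TE copy contributes (essentially) zero
antisense coverage -- a useful negative control that the test suite
exploits.

`maxMismatch` (default 0) switches to Hamming-tolerant window matching.
Hamming rather than edit distance was an open design choice; it is the
cheaper, deterministic option, it reproduces exact matching at 0, and
the choice is stamped into every output header
(`mismatch_metric=hamming`).

# LTR dating

The two LTRs of a provirus are identical at integration and drift
independently afterwards, so their pairwise divergence K accumulates at
twice the neutral rate. Age follows the standard clock inversion

$$ T = \frac{K}{2r} $$

with `r` in substitutions/site/Myr (default `0.0346`, the Drosophila
neutral rate under ten generations per year; the generation-time
assumption is folded into `r`, so no further conversion appears
anywhere). K defaults to Jukes-Cantor-corrected divergence
$K = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, the convention of the
classical LTR-dating literature; raw p-distance is available via
`model = "p"`. Gapped alignment columns are excluded (pairwise
deletion): indel rates are not part of the substitution clock. `p`
at or beyond 0.75 is a domain error, not a clamped value.

LTR copies are located by anchored alignment of the reference LTR
against terminal windows of the insertion spanning 150% of the LTR
length; an anchored identity below 60% classifies the insertion as
solo/truncated, which cannot be dated and is reported as such rather
than with a fabricated age.

**Resolution limit.** With L ungapped LTR columns the estimate is
quantized: one observed difference equals K = 1/L, i.e. steps of
$10^6/(2rL)$ years -- 36.1 kyr at L = 400, r = 0.0346. Insertions
younger than a few steps therefore carry large *relative* error no
matter how good the estimator is; the package reports exact K and
leaves interpretation of very young ages (including exactly zero
divergence) to the analyst. The validation suite measures this
directly: at a true age of 500 kyr the median relative error across
200 simulated insertions is about 19%, while at 50 kyr the
quantization floor alone is 28%.

# ORF integrity and env-F loss

Each annotated reference ORF (gag, pol, env-F) is located within an
insertion by one global alignment of the insertion to the consensus
(shared scoring everywhere: match +1, mismatch -1, gap open 5, extend
1); the region is then compared to the reference ORF and every indel
and every substitution creating an in-frame stop is reported in
reference-ORF coordinates. Indels are left-aligned in homopolymer
context so coordinates are deterministic. For each event the first
downstream in-frame stop of the query -- in the frame induced by all
upstream events -- is reported as a 1-based codon index, which is how
a frameshift followed by a premature stop is summarized.

An ORF is *intact* when it carries no frameshift or premature stop and
its uninterrupted reading length reaches at least 90% of the reference
ORF. The 90% threshold is this package's operational choice (no
numeric definition exists in the literature the method follows): it
tolerates terminal raggedness from alignment-boundary noise while
rejecting genuine truncations. Classes follow the retroviral logic:
`retrovirus_active` (gag, pol, env-F all intact), `retroelement_active`
(gag and pol intact, env-F lost -- the transposition-competent,
non-infectious state), otherwise `inactive`.

*env-F remnants* in retroelements are found by translating the region
from the 3' end of pol to the 3' LTR in all three forward frames and
locally aligning each translation (Smith-Waterman, BLOSUM62, gap open
11 / extend 1) against a reference Env protein. One best hit per frame
is kept at `minScore >= 60` by default; hits overlapping by more than
half of the shorter hit are resolved greedily by score, while smaller
overlaps are tolerated because local alignments bleed a few residues
across frameshift junctions. A remnant interrupted by a frameshift
thus appears as two hits in adjacent frames with near-abutting
reference intervals.

# Variant typing and recombination calling

Retroviral capsids are pseudo-diploid; when two variants replicate in
the same cell, reverse transcriptase can switch templates between the
co-packaged genomes. Two independent signals betray such recombinants:

- **Mismatched LTR types.** Each extracted LTR is typed against a
  variant library by global-alignment identity (best variant;
  ties broken by length difference, then name; below 80% identity the
  LTR is `untyped`). Differing 5'/3' types flag a recombinant; an
  untyped side yields an indeterminate result, never a mismatch.
- **Parental painting at diagnostic sites.** Given two insertions of
  each parental type in an MSA, diagnostic sites are columns where each
  pair shares a fixed allele and the two alleles differ; the gap symbol
  is a valid allele, and consecutive columns of one indel event are
  collapsed to the event's first column so one biological variant
  contributes one site. The query is called A, B or non-reference at
  each site; non-reference calls are reported but ignored for
  segmentation. Parental runs of at least `minSitesPerSegment`
  (default 2) sites form segments -- a single-site run never creates a
  segment, which makes the caller robust to isolated convergent
  mutations -- and each template switch is reported as the open column
  interval between the flanking diagnostic sites of adjacent segments.
  No point estimate is reported: resolution is bounded by informative
  sites. A variant type with only one good complete sequence may be
  supplied as a degenerate pair (`a1 == a2`), which is flagged in the
  output.

Per-column MSA summaries (`siteFrequencyProfile`) report occupancy and
the ranked non-gap symbol frequencies per column, with rank ties broken
lexicographically for reproducibility.

# The synthetic-data generator

The generator exists so that every stage can be validated offline
against known truth, and it encodes exactly the generative assumptions
the analyses invert:

- `simConsensus` builds LTR5 + UTR5 + gag + pol + env-F + UTR3 + LTR3
  with identical LTRs and ATG-initiated, internally stop-free,
  stop-terminated ORFs. Defaults (400 nt LTR, 200 nt 5' UTR,
  900/1500/900 nt ORFs, 150 nt 3' UTR) give a compact but structurally
  complete errantivirus-like element; uniform base composition
  minimizes chance k-mer hits in fixtures.
- `evolveInsertion` places Poisson(r * T * L) substitutions uniformly
  and independently on each LTR and on the internal sequence
  (JC-symmetric target base). No indel evolution: the dating model is
  substitution-only, and keeping the generator to the same model keeps
  the truth exact.
- `assembleCluster` interleaves random spacers with oriented consensus
  fragments; the truth table pins each fragment's consensus interval
  and cluster placement, from which expected antisense coverage
  follows up to at most k-1 junction positions per fragment end.
- `simVariant` derives a variant haplotype by fixed substitutions and
  copies the variant's 5' LTR over its 3' LTR -- a variant lineage
  carries its own LTR at both ends, which is what makes LTR-mismatch
  detection of recombinants well-posed.
- `makeRecombinant` splices two homologous parents at given
  coordinates (equal-length parents map 1:1; otherwise the shared
  aligner maps homologous coordinates).
- `injectInactivation` applies a single indel or stop substitution
  inside a named ORF, by default shifted to a non-homopolymer position
  so the alignment placement -- and hence the recorded coordinate --
  is unambiguous; any shift is recorded in the truth.

Identical seeds give byte-identical sequences and truth tables; the
pipeline derives per-stage seeds from one config seed so stages are
independently reproducible.

What the generator does *not* emulate: insertion-site duplication and
flanking genomic context, nested insertions, solo-LTR formation,
selection, indel evolution outside injected events, and non-uniform
base composition. Tests passing on synthetic data therefore demonstrate
correctness of the computations under the stated model, not robustness
to every artifact of real genomic extractions (e.g. heavily nested or
internally deleted copies still need curation upstream).

# Numerical and validation choices

- One shared nucleotide aligner contract everywhere (match +1,
  mismatch -1, gap open 5, extend 1) so coordinates agree across
  modules; protein local alignment uses BLOSUM62 with open 11 /
  extend 1.
- Validation problem sizes: the coverage implementation is compared
  with a naive every-window-against-every-window oracle on 200 random
  fixtures of 80-420 nt; dating recovery uses 200 simulated insertions
  per true age in {50, 150, 500} kyr; recombination calling uses 100
  parent/recombinant panels (alternating single and double switches,
  at least 10 diagnostic sites per segment); ORF-event recovery uses
  100 injected events across gag/pol/env-F. These sizes give stable
  medians and proportions while keeping the whole suite fast.
- Degenerate inputs fail loudly: empty FASTA, duplicate ids, `.` gap
  characters, zero ungapped alignment columns, p >= 0.75 under JC69,
  breakpoints outside the parent, positions outside the ORF.

# Limitations

- `classifyIntegrity` assumes the insertion is colinear with the
  consensus (one global alignment); large rearrangements should be
  handled upstream.
- `findEnvRemnants` keeps one local hit per reading frame; several
  disjoint remnants in the *same* frame are reported as the single
  best-scoring one.
- Breakpoint intervals, not points: two switches falling between the
  same pair of adjacent diagnostic sites are indistinguishable and are
  called as at most one.
- The dating clock is single-rate and substitution-only; codon-aware
  or multi-rate clocks, orthologous-flank dating and
  population-frequency dating are out of scope.
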