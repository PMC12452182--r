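---
title: "Classifying contiguous riboswitch architectures and testing their enrichment"
author: "riboArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying contiguous riboswitch architectures and testing their enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboArch)
```

## The problem

Riboswitches are cis-regulatory RNA elements in the 5' region of
prokaryotic transcripts: a ligand-sensing aptamer coupled to an
expression platform that switches transcription or translation of the
downstream gene.  Usually one riboswitch regulates one gene, but some
intergenic regions carry two or more aptamers.  Two architectures are
distinguished:

* **tandemly arranged riboswitches** — two or more complete units,
  each with its own aptamer and platform; the first unit typically
  ends in a Rho-independent (intrinsic) transcription terminator;
* **riboswitches with adjacent aptamers** — two or more sensor
  domains followed by a single shared platform (the glycine riboswitch
  is the canonical example).

riboArch classifies aptamer hit collections into these architectures
and quantifies, with one-sided hypergeometric tests, which phyla,
ligand families and orthologous gene groups (COGs) are enriched for
each configuration.

## Pipeline and models

### Inputs and conventions

Gene annotations enter as GFF3 or a simple TSV dialect; covariance-model
aptamer hits enter in Infernal `cmsearch --tblout` format; sequences as
FASTA.  Internally everything lives in Bioconductor containers
(`GRanges`, `DNAStringSet`) with 1-based inclusive coordinates; format
conversions happen only at the I/O boundary.  Upstream intergenic
regions are extracted strand-aware and minus-strand sequences are
stored reverse-complemented, so all downstream windowing runs in
transcript orientation.  When two divergently transcribed genes share
a gap, each receives its own (possibly coinciding) upstream region —
the attribution is ambiguous in principle and this choice keeps every
gene analysable.

### Empirical bit-score cutoffs

Curated per-family gathering thresholds can be too stringent for some
aptamer families, so cutoffs are re-derived empirically: every
intergenic region is shuffled 100 times preserving its dinucleotide
composition, the shuffles are scanned with the covariance model, and
the cutoff is the highest bit score noise attains (strictly greater
scores survive filtering, since the maximum random score is by
construction attainable by noise).  The shuffler uses the Euler-path
(Altschul–Erickson) construction, which exactly preserves the
dinucleotide multiset, hence length, base composition and the first
and last letter.  Shuffling is per region by default, preserving local
composition and length simultaneously; a pooled first-order Markov
mode (`mode = "genome"`) resamples length-matched sequences from the
whole collection instead.  Non-ACGT letters are rejected rather than
resampled: silent composition distortion is worse than an explicit
failure, and ambiguous stretches can be hard-masked upstream.  When no
random hit occurs at all the cutoff floor is 0 bits, a deliberately
permissive value that lets a curated threshold supplied by the caller
dominate.  Cutoffs are per model; one root seed spawns a derived
substream per (region, replicate), so results are independent of
evaluation order.

### Terminator detection

The detector scans a 50-nt window downstream of an aptamer.  A T-run
is any merged set of 6-nt windows containing at least 5 T residues
(clipped to its first and last T); the run-length sliding-window
formulation, with both numbers exposed as parameters, is the standard
intrinsic-terminator heuristic.  Hairpins are folded by a built-in
dynamic programme over the single-stem structure class: nested pairs
(Watson–Crick and G·U), bulges and internal loops up to 3 nt per
side, no multiloops, scored with Turner-style stack free energies and
tabulated hairpin/bulge/internal-loop initiation penalties at 37 °C
(no dangles or terminal-pair corrections — terminator stems are GC-rich
and these refinements do not move calls at the −10 kcal/mol scale).
Restricting to single stems keeps the optimisation exact and
dependency-free while staying on the kcal/mol scale the threshold
assumes.

A call requires, for some T-run taken 5'→3', that the **most stable**
hairpin of the window portion *before* the run ends at most 2 nt
before the run start with a free energy strictly below −10 kcal/mol.
Two aspects of this rule were genuinely open and are the package's own
choices:

* *Most stable, not merely stable enough.*  Accepting any
  above-threshold hairpin anchored near a run roughly doubles the
  false-positive rate on dinucleotide-shuffled sequence (such shuffles
  conserve G/C/T runs and therefore much of the terminator signal);
  requiring the optimum mirrors folding the window and inspecting its
  minimum-free-energy structure.
* *Before the run.*  The U-tail of an intrinsic terminator is
  single-stranded, so structure downstream of the T-run must not
  compete with the candidate hairpin (otherwise a planted terminator
  inside an A-rich host is masked by spurious A:U pairing with its own
  tail).

Co-optimal hairpins resolve toward the run (smallest gap, then
5'-most); the first T-run with a qualifying hairpin wins.  Between two
aptamers the window is clipped so it never reads into the next aptamer
or the coding sequence.

### Architecture classification

Hits overlapping by more than half the shorter hit are redundant model
matches; only the best (bit score, then E-value, then model name)
survives.  Hits sharing an intergenic region form one contiguous
group; junction gaps are measured from the end of the upstream aptamer
to the start of the downstream one — the only reading under which a
terminator can fit *between* the aptamers.  A junction with a gap
below 20 nt is `adjacent` (too narrow to host an expression
platform), otherwise `tandem`; a gap of exactly 20 nt is tandem, since
"closer than 20" defines adjacency.  The distance rule is
authoritative; terminator calls are recorded as per-junction
supporting evidence but never override it — making both authoritative
would contradict every ≥20-nt junction whose terminator simply evades
detection.  Groups whose junctions disagree get an explicit `mixed`
class.  Homogeneity compares ligand families (via the packaged
50-class → 27-family map, a reconstruction in which the SAM and
c-di-GMP memberships and the named singleton families follow the
published description): `homogeneous` when all aptamers sense the same
ligand family.

### Enrichment analyses

Thirteen catalogued analyses (S6–S19) stratify riboswitch, contiguous,
tandem and adjacent counts by phylum, family, family-within-phylum,
COG and COG-within-phylum.  Every test is the one-sided upper tail
`P(X >= k)` of a hypergeometric draw — the probability of observing
the same or a greater number of successes — computed with
`stats::phyper`.  Riboswitch-denominated rows count aptamer instances
after deduplication; gene-denominated rows count distinct regulated
genes (a gene under two aptamers counts once).  Raw p-values are the
primary output, matching the convention of reporting unadjusted
hypergeometric probabilities; a Benjamini–Hochberg column is available
as an opt-in convenience but never drives the ordering.  `mixed`
groups count as contiguous but as neither tandem nor adjacent.

## The synthetic collection generator

`simulateCollection()` emulates exactly the statistical structure the
analyses assume: phyla with independent per-gene regulation rates
(base rate times per-phylum and per-COG multipliers), an architecture
mix over single / tandem-pair / adjacent-pair / tandem-triple, family
sampling weights with a 70% propensity to repeat the previous family
within a group (so both homogeneous and heterogeneous groups occur),
tandem junction gaps of 30–50 nt and adjacent gaps of 5–15 nt (both
clear of the 20-nt boundary by at least 5 nt, so classification is
unambiguous by construction), and a canonical terminator — 8-bp G:C
stem, 4-nt loop, 8-nt T-tail — planted at every tandem junction by
default.  Background sequence comes from a first-order Markov chain
with configurable GC and mild same-base persistence.  Regulated genes
are laid out so that their planted region is flanked by gene bodies,
which makes `extractIntergenic()` reproduce the planted regions
byte-for-byte; a fraction of unregulated genes sits on the minus
strand.  All randomness flows from one seed through named per-genome
substreams.

Default dimensions are 5 phyla × 4 genomes × 200 genes with a 5%
regulation rate — a desk-scale collection dense enough to yield a few
hundred groups in seconds.  A `level = "counts"` mode skips sequence
synthesis and scales to millions of genes for calibration studies.

What the generator deliberately does **not** emulate: covariance-model
emission (hits are planted coordinates with scores, not alignable
sequence), phylogenetic correlation between genomes, operonic gene
structure, and overlapping or nested real-world annotations.  Passing
the recovery suites therefore demonstrates the correctness of the
classification and testing machinery under the stated model, not the
sensitivity of covariance-model search on real genomes.

## Numerical and calibration checks

The test suite verifies each numeric engine against an independent
oracle: the hypergeometric tail against direct `choose()` summation
over the full grid of population sizes up to 60; the hairpin dynamic
programme against exhaustive enumeration of every legal single-stem
structure on 1,000 random 15–25-mers; the shuffler against a
dinucleotide-counting oracle on 10,000 sequences (and, for short
sequences, against complete enumeration of the reachable set).

Two statistical properties document the enrichment layer.  Under a
null collection (20 phyla × 10 genomes × 500 genes, rate 0.02, one
riboswitch per regulated gene — conditions under which the per-phylum
counts are exactly multivariate hypergeometric and per-stratum draws
have expectation ≈100, keeping discreteness mild), the fraction of
strata with p < 0.05 over 200 replicates sits within three standard
errors of 5%.  With a five-fold rate multiplier on one phylum in a
20 × 50 × 2,000-gene collection, that phylum attains the smallest
p-value, below 1e−6, in every replicate.  The terminator detector's
false-positive rate on dinucleotide-shuffled planted windows averages
about 8% (seeded measurement; such shuffles retain G/C/T runs, so
this documents specificity against locally realistic noise, not
against uniform random sequence, where the rate is far lower).

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `windowLen` | 50 | nt | analysis window downstream of an aptamer |
| `tRunMinT` / `tRunWindow` | 5 / 6 | nt | T-run rule |
| `dgThreshold` | −10 | kcal/mol | strict bound on hairpin stability |
| `maxGap` | 2 | nt | spacer between hairpin base and T-run |
| `minStem` / `minLoop` | 3 / 3 | bp / nt | minimal stem-loop geometry |
| `adjacencyThreshold` | 20 | nt | gap below ⇒ adjacent aptamers |
| `overlapFrac` | 0.5 | — | redundancy fraction for deduplication |
| `nShuffles` | 100 | — | shuffles per region for calibration |

Degenerate inputs behave conservatively: windows too short for a stem
plus run yield no call; empty strata yield no task; `k = 0` yields
p = 1 exactly; homopolymers shuffle to themselves; a gap of zero
between genes yields no intergenic region.

## Limitations

Hit scores are consumed, never computed — running covariance-model
search is out of scope.  The folding engine is hairpin-only; it is not
a general secondary-structure predictor and its free energies should
not be compared with full-model predictions beyond the stem-loop
class.  Reproducing database-scale counts (tens of thousands of
riboswitches across thousands of genomes) requires the original
genome collection and is likewise out of scope; the acceptance
machinery instead re-derives the printed worked-example percentages
and validates every engine at desk scale.
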