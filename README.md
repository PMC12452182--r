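# riboArch

Classification of contiguous riboswitch architectures and
hypergeometric enrichment analysis for prokaryotic genome collections.

## Scientific problem

Riboswitches are cis-regulatory RNA elements in the 5′ region of
bacterial and archaeal transcripts: a ligand-sensing **aptamer**
coupled to an **expression platform** that attenuates transcription or
translation of the downstream gene. Occasionally a single intergenic
region carries several aptamers, in one of two architectures:

* **tandemly arranged riboswitches** — ≥2 complete units, each with
  its own platform; the first unit typically ends in a Rho-independent
  (intrinsic) transcription terminator;
* **riboswitches with adjacent aptamers** — ≥2 sensor domains sharing
  a single platform after the final aptamer.

riboArch is for computational biologists who have gene annotations,
intergenic sequences and covariance-model aptamer hits (Infernal
`cmsearch --tblout`), and want to (i) calibrate empirical bit-score
cutoffs by dinucleotide-preserving shuffling, (ii) detect intrinsic
terminators between aptamers, (iii) classify contiguous groups, and
(iv) test enrichment of architectures across phyla, ligand families
and orthologous gene groups (COGs).

## Models at the core

**Architecture rule.** Aptamer hits sharing an intergenic region form
one contiguous group. A junction with inter-aptamer gap *g* < 20 nt is
*adjacent* (too narrow to host an expression platform); *g* ≥ 20 nt is
*tandem*. Terminator detections are recorded as supporting evidence per
tandem junction.

**Terminator model.** In the 50-nt window downstream of an aptamer, a
call requires a T-run (≥5 T within a 6-nt sliding window) preceded, at
a gap of ≤2 nt, by the most stable stem-loop of the pre-run sequence
with ΔG° < −10 kcal/mol. Hairpins are folded by a built-in
single-stem minimum-free-energy dynamic programme (Turner-style
nearest-neighbour stacks, G·U wobbles, bulges/internal loops ≤3 nt per
side).

**Enrichment.** Every analysis is the upper-tail hypergeometric
probability — for a population of N elements containing K successes
and a group of n elements with k successes,

P(X ≥ k),  X ~ Hypergeometric(N, K, n)

— the probability of observing the same or a greater number of
occurrences. Thirteen catalogued analyses (S6–S19) stratify riboswitch,
contiguous, tandem and adjacent counts by phylum, family and COG.

A synthetic-collection generator (`simulateCollection()`) plants
aptamer hits, architectures, junction gaps and canonical terminators
with known ground truth, so the whole pipeline is testable without any
database download.

## Worked example

Simulate a collection with planted ground truth, write it to disk in
the standard formats, and run the full pipeline:

```r
library(riboArch)

sim <- simulateCollection(simConfig(seed = 42))
d <- file.path(tempdir(), "demo")
writeCollection(sim, d)   # genes.tsv, regions.fasta, hits.tbl, truth.json

res <- runPipeline(file.path(d, "genes.tsv"),
                   file.path(d, "regions.fasta"),
                   file.path(d, "hits.tbl"),
                   file.path(d, "out"),
                   analyses = c("S6", "S9", "S10"))
res$groups
#> ContiguousGroupSet: 301 groups, 463 aptamers
#> classes: adjacent=39, single=172, tandem=90
```

301 intergenic regions hold at least one aptamer; 129 hold several.
Each multi-aptamer group carries its 5′→3′ family string, junction
gaps and terminator evidence:

```r
head(groupTable(res$groups)[groupTable(res$groups)$n_aptamers > 1, ], 3)
#>               region_ref architecture_string group_class homogeneity
#>  igr|g01_01|g01_01_g0033         T-box T-box    adjacent homogeneous
#>  igr|g01_01|g01_01_g0038     Glycine Glycine      tandem homogeneous
#>  igr|g01_01|g01_01_g0112             SAM SAM      tandem homogeneous
#>  junction_gaps terminator_evidence
#>             14               FALSE
#>             42                TRUE
#>             46                TRUE
```

The first group's aptamers sit 14 nt apart — below the 20-nt bound, so
they are adjacent sensor domains; the other two have room for (and
detectable) terminators between the units. Enrichment of tandem
arrangements per phylum (analysis S9):

```r
head(res$enrichment[res$enrichment$analysis == "S9", ], 3)
#>   analysis  stratum    N   K   n  k      fold    p_value
#> 9       S9 Phylum04 4000 213 800 55 1.2910798 0.02024956
#> 6       S9 Phylum01 4000 213 800 47 1.1032864 0.24357866
#> 8       S9 Phylum03 4000 213 800 40 0.9389671 0.70348629
```

Phylum04 carries 55 of the 213 tandem-arranged aptamers over its 800
of 4,000 genes (1.29-fold over expectation, p = 0.02) — an unremarkable
fluctuation under this null simulation, as expected.

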