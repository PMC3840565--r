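---
title: "Comparative mapping of draft genomes: anchoring, homologous chromosomes and conserved synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mapping of draft genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

## The problem

Many economically important fish species have rich but fragmented genome
resources — a genetic linkage map with microsatellite markers derived from
BAC clones, a fingerprinted BAC physical map, BAC end sequences (BES),
physical-map contig-specific sequences (PMCSS), and a draft assembly of
unordered scaffolds — but no chromosome-level reference. Comparative
mapping transfers positional information from fully sequenced model fish
genomes (zebrafish, medaka, stickleback, *Tetraodon*) onto such a draft
genome. synmapr implements that workflow as four analysis stages plus a
ground-truthed simulator:

1. **Anchoring.** A scaffold is placed on a linkage group when a complete
   evidence chain exists: a mapped microsatellite marker identifies its
   source BAC; the BAC identifies a physical-map contig; the contig's
   anchor sequences (BES or PMCSS) match the scaffold. Scaffolds supported
   by several markers on one linkage group take the median cM position;
   scaffolds supported by more than one linkage group are flagged
   `CONFLICT` and, by default, excluded. The published record of this
   strategy does not say whether (or how) such conflicts were resolved, so
   the policy is explicit, logged, and switchable
   (`conflictPolicy = "best-support"` keeps the linkage group with the
   most chains).
2. **Homolog identification.** Protein-level alignment hits of scaffold
   sequence against a model proteome are filtered at an e-value cutoff of
   `1e-10`. The cutoff is inclusive (`evalue <= 1e-10` survives); the
   customary phrase "cutoff of 1e-10" does not fix the boundary, so the
   inclusive reading is documented here once and used everywhere. Hits on
   one scaffold whose query intervals overlap (or fall within
   `minIntervalSeparationBp`) are clustered into one putative gene
   interval, and each interval keeps its best hit (highest bitscore, then
   lowest e-value, then lexicographically smallest subject). How exactly
   overlapping HSPs were merged into unique gene counts is the largest
   under-determined step of the original workflow; the interval-clustering
   rule is this package's explicit choice and the separation window is a
   configuration knob. A gene hit by scaffolds on two linkage groups is
   counted in each (the overlap size is logged).
3. **Homologous chromosomes.** The Oxford grid cell (LG, chr) is the
   percentage of a linkage group's unique *chromosome-placed* homologs
   located on a model chromosome. Genes without chromosome placement
   (`UNPLACED`) are excluded from the denominator — model annotations
   always carry some fraction of unplaced genes, and the paired
   placed/total accounting per linkage group keeps that visible.
   Chromosomes holding strictly more than 10% of a linkage group's placed
   homologs are homologous segments; cells strictly above 30% are "major"
   (the conventional yellow class in rendered grids), cells in (10, 30]
   "minor" (orange). Both thresholds read "more than" as a strict
   inequality. Fusion-like patterns (one linkage group built from k > 1
   chromosomes that each map back predominantly to it) and the symmetric
   fission-like patterns are called from the two directions of the same
   grid.
4. **Conserved synteny.** A conserved block requires at least two genes
   that are adjacent on a model chromosome and co-located in a single
   scaffold. Within each (scaffold, model chromosome) pair, genes are
   sorted by model rank and partitioned into maximal runs with successive
   rank differences at most `1 + maxRankGap`; `maxRankGap = 0` (strict
   adjacency) is the default. Adjacency ranks come from the full
   annotation by default (`ALL_ANNOTATED`): "adjacent genes on the model
   chromosome" most literally means neighbours in the annotation. The
   `HIT_ONLY` universe re-ranks over genes with at least one assignment,
   so genes that simply failed to be hit do not break biologically
   contiguous runs; whether the original analysis bridged such gaps
   cannot be determined, hence the knob. Blocks never span two scaffolds,
   even when scaffolds stack at one cM. Block order within a scaffold is
   not required to be colinear — the rule is co-location plus model
   adjacency, because gene order inside a stacked scaffold region is
   unresolvable on a low-resolution map.

Block spans are measured in **model-species coordinates** (first gene
start to last gene end). Draft-genome coordinates of an unpublished
assembly are not generally available, while model coordinates always are;
the simulator additionally records target-coordinate spans for every truth
segment, so both views exist where both genomes are known.

## The simulator and what it emulates

`simulateComparativeGenomes()` generates a model genome with a
deterministic layout (gene *i* starts at
$(i-1)(L_\mathrm{gene}+L_\mathrm{gap})+1$), applies a rearrangement
history, fragments the result into scaffolds and emits every input table
the pipeline consumes, plus ground truth (event log, per-scaffold truth
segments). Design choices, each fixed once:

* **Gene-order space.** Events permute gene orders; coordinates are
  re-laid-out afterwards. The analysis is gene-order based, so base-pair
  breakpoint realism adds nothing testable.
* **Event order** is fusions → fissions → inversions → translocations →
  loss, each drawing from an independent sub-stream of the seed, so event
  logs are reproducible and one stage's settings cannot perturb another's
  draws. That independence is what makes the noise-invariance property
  (spurious hits above the cutoff change nothing) testable at all.
* **At most one membership-changing event per chromosome.** Fusions and
  fissions pick distinct model chromosomes. Stacked fusion-then-fission
  histories produce composite patterns that no pairwise grid method can
  attribute to individual events; keeping the histories separable is what
  lets recovery be scored exactly against the log.
* **Fission breakpoints** are drawn from the central 20–80% of the gene
  order: real fissions must leave two viable chromosomes, and a split
  shaving off 2% of a chromosome is neither realistic nor detectable by a
  percentage-threshold method.
* **Inversions span 2–50 genes, translocated segments 1–20 genes** —
  small segmental events of the kind seen within conserved fish
  karyotypes, and small relative to the 400-gene chromosomes they act on.
* **Map geometry.** cM positions are a linear function of physical
  position (100 cM/Mb on the deliberately small desk-scale chromosomes,
  keeping map lengths in a realistic tens-of-cM range) binned at
  `mapResolutionCm` = 0.5 cM. The binning reproduces the *stacking* of
  scaffolds at identical map positions that a low-resolution linkage map
  causes, which the synteny stage must tolerate.
* **Noise model.** True hits draw e-values at or below 1e-20 and
  bitscores proportional to gene length; paralog hits (same chromosome,
  strictly lower bitscore, e-value still under the cutoff) probe the
  best-hit rule; spurious hits draw e-values in (1e-10, 1e-2] so the
  canonical filter removes exactly them. The spurious and paralog rates
  are free testing parameters — no claim is made that they estimate the
  noise of any real data set.

What the simulator does **not** emulate: nucleotide sequences (no
alignment is performed; the hit table stands in for an upstream BLASTX
run), indel/substitution evolution, repeat content, assembly errors, or
marker genotyping error. Passing recovery tests therefore demonstrates the
correctness of the *logic* — chain-walking, filtering, clustering,
thresholds, run partitioning — not robustness to every artefact of real
draft assemblies.

### Truth segments

A truth segment is a maximal run of genes with consecutive model ranks
inside one scaffold — the same set-based definition the detector uses.
With rearrangement, set-based runs and target-order runs genuinely differ:
an inversion interior inside one scaffold is a single consecutive-rank run
whose target order is reversed, and a translocation can interleave two
runs. Truth segments therefore carry genes in model-rank order, and their
consistency guarantee is that each scaffold's segments partition its gene
content exactly (no gene lost, duplicated or misassigned). Block/truth
matching is by gene set within (scaffold, chromosome).

## Numerical and degenerate-input conventions

* N50 uses the standard rule (largest L with elements ≥ L covering half
  the total); ties resolve to the first qualifying length in descending
  order; an empty set has N50 = 0 and an empty assembly anchors 0%.
* Rendered percentages and Kb/gene display values round half *up*
  (`roundHalfUp()`), matching the integer display convention of published
  Oxford grids; full precision is retained in every object.
* Readers are strict by default (malformed rows are errors naming the
  line; duplicate marker ids and dangling scaffold references are
  errors); `strict = FALSE` downgrades these to logged warnings.
  Reproducibility argues for strict-by-default.
* Empty detections against non-empty truth score precision 1 (vacuously)
  and recall 0; the exact-match fraction is the Jaccard index of the two
  block-key sets.

## Problem sizes used in the validation suite

The packaged checks run at desk scale, chosen to exercise every code path
while keeping a full run in seconds-to-minutes: unit fixtures of a few
genes; property checks over hundreds of random fixtures of up to a few
thousand genes; and an end-to-end recovery study of 25 chromosomes × 400
genes (10,000 genes) with 2 fusions, 2 fissions, 5 inversions and 5
translocations, on which block detection and fusion/fission calling are
scored exactly against the generator's truth. The bundled published
per-linkage-group block summary (29 linkage groups) supports the
aggregation checks; its raw underlying data are not public, so those
checks validate in-table arithmetic, not re-derivation.

## A worked run

```{r example}
cfg <- simConfig(seed = 7, nChromosomes = 6, genesPerChromosome = 60,
                 nFusions = 1, nFissions = 1, nInversions = 2,
                 nTranslocations = 2)
sim <- simulateComparativeGenomes(cfg)
sim

ev <- evidenceTables(sim)
anc <- buildEvidenceChains(markerTable(sim), ev$bacContig,
                           ev$contigAnchors, ev$seqScaffold,
                           scaffolds = scaffoldIndex(sim)[, 1:2])
computeAnchorStats(scaffoldIndex(sim)[, 1:2], anc)

lga <- homologsPerLinkageGroup(
  assignBestHits(filterHits(hitTable(sim)[, 1:6]), modelAnnotation(sim)),
  anc)
m <- buildHomologyMatrix(lga)
detectFusionFission(m)

blocks <- detectSyntenyBlocks(lga, modelAnnotation(sim))
unlist(compareToTruth(blocks, truthSegments(sim))[1:3])
```

## Known limitations

* Percentage-threshold homology assignment cannot attribute overlapping
  rearrangement histories (e.g. a fission of a previously fused
  chromosome) to individual events; such patterns surface as `complex`.
* The conflict policy for multi-linkage-group scaffolds is a modelling
  decision, not an inference; both policies are exposed precisely because
  the right answer depends on the quality of the underlying map.
* Spans in model coordinates understate blocks whose target-side extent
  differs (e.g. after local expansion); where target coordinates exist
  (simulation), truth segments carry both.
* The MapChart export implements the minimal dialect (group headers and
  name/position rows); colours, fills and chart layout directives are out
  of scope.
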