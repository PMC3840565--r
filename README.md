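# synmapr

Whole-genome comparative mapping for draft (scaffold-level) genomes
against fully sequenced model species — the situation of most aquaculture
fish genomes, where a genetic linkage map, a BAC physical map, BAC end
sequences (BES), physical-map contig-specific sequences (PMCSS) and an
unordered draft assembly exist, but no chromosome-level reference.

The package implements four analysis stages and a ground-truthed
simulator:

* **Anchoring** — scaffolds are placed on linkage groups via the evidence
  chain *marker → source BAC → physical-map contig → anchor sequence
  (BES/PMCSS) → scaffold*; multi-marker support takes the median cM,
  multi-linkage-group support is flagged `CONFLICT`. Assembly statistics
  use the standard N50 rule
  (N50 = max { L : Σ<sub>ℓ≥L</sub> ℓ ≥ ½ Σ ℓ }).
* **Homology** — alignment hits (BLAST outfmt-6 tabular) filtered at
  e ≤ 1e-10, clustered into query intervals per scaffold, one best hit per
  interval (bitscore ↓, e-value ↑, subject id); per-linkage-group unique
  homolog counts, total and chromosome-placed.
* **Homologous chromosomes** — an Oxford grid with cell
  (LG, c) = 100 · |unique placed homologs of LG on c| / |unique placed
  homologs of LG|; chromosomes with cells > 10% are homologous segments,
  cells > 30% are major; fusion-like / fission-like patterns are called
  from the two grid directions.
* **Conserved synteny** — blocks are maximal runs of genes with
  consecutive model-chromosome ranks co-located in a single scaffold
  (≥ 2 genes; rank gap tolerance and adjacency universe configurable),
  with per-linkage-group summaries (counts, spans in model coordinates,
  span N50, gene counts).
* **Simulator** — a seeded generator derives a target genome from a model
  genome by fusions, fissions, inversions, translocations and gene loss,
  fragments it into scaffolds with full anchoring evidence and a noisy
  hit table, and records ground truth (event log, truth segments) for
  exact validation of every stage.

## Worked example

```r
library(synmapr)

cfg <- simConfig(seed = 7, nChromosomes = 6, genesPerChromosome = 60,
                 nFusions = 1, nFissions = 1, nInversions = 2,
                 nTranslocations = 0)
sim <- simulateComparativeGenomes(cfg)

ev  <- evidenceTables(sim)
anc <- buildEvidenceChains(markerTable(sim), ev$bacContig,
                           ev$contigAnchors, ev$seqScaffold,
                           scaffolds = scaffoldIndex(sim)[, 1:2])
computeAnchorStats(scaffoldIndex(sim)[, 1:2], anc)
#> AnchorStats
#>   scaffolds: 17 (N50 50,000 bp, span 720,000 bp)
#>   anchored:  17 (N50 50,000 bp, span 720,000 bp, 100.0% of assembly)

lga <- homologsPerLinkageGroup(
  assignBestHits(filterHits(hitTable(sim)[, 1:6]), modelAnnotation(sim)),
  anc)
detectFusionFission(buildHomologyMatrix(lga))
#>           type focal k  partners
#> 1  fusion-like   LG4 2 chr1;chr5
#> 2 fission-like  chr4 2   LG5;LG6

blocks <- detectSyntenyBlocks(lga, modelAnnotation(sim))
unlist(compareToTruth(blocks, truthSegments(sim))[1:3])
#>            precision               recall exact_match_fraction
#>                    1                    1                    1
```

The anchoring summary says all 17 simulated scaffolds (720 kb) carry a
complete evidence chain. The pattern calls recover the simulated fusion
(`LG4` built from `chr1` + `chr5`) and fission (`chr4` split across
`LG5`/`LG6`) exactly, and every detected synteny block matches a
ground-truth segment (precision = recall = 1).

On tiny chromosomes like these, translocated segments (1–20 genes) can
exceed the 10% segment threshold and surface as additional `complex`
calls; at the package's default validation scale (400-gene chromosomes)
they stay below it, as a small segmental translocation should.

`runPipeline("config.yaml", outdir = "out")` chains every stage from a
YAML configuration (simulated or file inputs) and writes all tables plus
a reproducibility manifest; `inst/scripts/synmap.R` wraps it for shell
use.

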