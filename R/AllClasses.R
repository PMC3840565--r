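#' @import methods
NULL

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic comparative-genome generator. The generator
#' lays out a model genome of `nChromosomes` x `genesPerChromosome` genes,
#' derives a target genome from it by chromosome fusions, fissions,
#' inversions and translocations plus per-gene loss, fragments the target
#' into scaffolds, places microsatellite markers on a genetic map (cM taken
#' as a linear function of physical position, then binned at
#' `mapResolutionCm`, which reproduces the stacking of scaffolds at shared
#' map positions), wires up the marker/BAC/physical-contig/anchor-sequence
#' evidence tables, and emits a noisy protein-alignment hit table.
#'
#' @slot seed integer; fixes every random draw (each internal stage uses an
#'   independent sub-stream derived from it).
#' @slot nChromosomes,genesPerChromosome integer; model genome layout.
#' @slot geneLengthBp,intergenicBp integer; deterministic gene spacing, gene
#'   i on a chromosome starts at `(i-1)*(geneLengthBp+intergenicBp)+1`.
#' @slot nFusions,nFissions,nInversions,nTranslocations integer; event
#'   counts. Fusion and fission targets are distinct chromosomes (at most
#'   one membership-changing event per chromosome).
#' @slot geneLossRate,spuriousHitRate,paralogRate probabilities in `[0,1]`.
#' @slot scaffoldN50Target integer; approximate scaffold N50 in bp.
#' @slot markerDensityPerMb numeric; markers per Mb of target sequence.
#' @slot mapResolutionCm numeric; cM bin width (stacking knob).
#' @slot cmPerMb numeric; map expansion constant converting physical Mb to
#'   cM before binning.
#' @slot anchorEvidenceRate probability that a scaffold receives a complete
#'   evidence chain (1 = every scaffold anchorable).
#' @slot besFraction probability an anchor sequence is a BAC end sequence
#'   rather than a physical-map contig-specific sequence.
#' @export
setClass("SimConfig", slots = c(
  seed = "integer",
  nChromosomes = "integer",
  genesPerChromosome = "integer",
  geneLengthBp = "integer",
  intergenicBp = "integer",
  nFusions = "integer",
  nFissions = "integer",
  nInversions = "integer",
  nTranslocations = "integer",
  geneLossRate = "numeric",
  spuriousHitRate = "numeric",
  paralogRate = "numeric",
  scaffoldN50Target = "integer",
  markerDensityPerMb = "numeric",
  mapResolutionCm = "numeric",
  cmPerMb = "numeric",
  anchorEvidenceRate = "numeric",
  besFraction = "numeric"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  rates <- c(geneLossRate = object@geneLossRate,
             spuriousHitRate = object@spuriousHitRate,
             paralogRate = object@paralogRate,
             anchorEvidenceRate = object@anchorEvidenceRate,
             besFraction = object@besFraction)
  bad <- rates[is.na(rates) | rates < 0 | rates > 1]
  if (length(bad))
    msgs <- c(msgs, sprintf("rate '%s' must be in [0,1]", names(bad)[[1L]]))
  counts <- c(object@nChromosomes, object@genesPerChromosome,
              object@geneLengthBp, object@nFusions, object@nFissions,
              object@nInversions, object@nTranslocations,
              object@scaffoldN50Target)
  if (any(is.na(counts)) || any(counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (object@nChromosomes < 1L || object@genesPerChromosome < 1L)
    msgs <- c(msgs, "need at least one chromosome and one gene per chromosome")
  if (object@geneLengthBp < 1L)
    msgs <- c(msgs, "geneLengthBp must be positive")
  if (object@intergenicBp < 0L)
    msgs <- c(msgs, "intergenicBp must be non-negative")
  if (object@mapResolutionCm < 0 || object@cmPerMb <= 0 ||
      object@markerDensityPerMb <= 0)
    msgs <- c(msgs, "map parameters must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Create a simulation configuration
#'
#' Defaults correspond to the validation conditions used throughout the
#' package: a 25-chromosome model genome of 400 genes per chromosome and a
#' rearrangement history of 2 fusions, 2 fissions, 5 inversions and 5
#' translocations, with no gene loss and a noise-free hit table.
#'
#' @param seed integer seed.
#' @param nChromosomes,genesPerChromosome,geneLengthBp,intergenicBp,nFusions,nFissions,nInversions,nTranslocations,geneLossRate,spuriousHitRate,paralogRate,scaffoldN50Target,markerDensityPerMb,mapResolutionCm,cmPerMb,anchorEvidenceRate,besFraction
#'   see the corresponding [SimConfig-class] slots.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nChromosomes = 3, genesPerChromosome = 20)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 25L,
                      genesPerChromosome = 400L,
                      geneLengthBp = 1000L,
                      intergenicBp = 1000L,
                      nFusions = 2L,
                      nFissions = 2L,
                      nInversions = 5L,
                      nTranslocations = 5L,
                      geneLossRate = 0,
                      spuriousHitRate = 0,
                      paralogRate = 0,
                      scaffoldN50Target = 50000L,
                      markerDensityPerMb = 20,
                      mapResolutionCm = 0.5,
                      cmPerMb = 100,
                      anchorEvidenceRate = 1,
                      besFraction = 0.3) {
  new("SimConfig",
      seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      genesPerChromosome = as.integer(genesPerChromosome),
      geneLengthBp = as.integer(geneLengthBp),
      intergenicBp = as.integer(intergenicBp),
      nFusions = as.integer(nFusions),
      nFissions = as.integer(nFissions),
      nInversions = as.integer(nInversions),
      nTranslocations = as.integer(nTranslocations),
      geneLossRate = geneLossRate,
      spuriousHitRate = spuriousHitRate,
      paralogRate = paralogRate,
      scaffoldN50Target = as.integer(scaffoldN50Target),
      markerDensityPerMb = markerDensityPerMb,
      mapResolutionCm = mapResolutionCm,
      cmPerMb = cmPerMb,
      anchorEvidenceRate = anchorEvidenceRate,
      besFraction = besFraction)
}

#' Homology-calling configuration
#'
#' @slot evalueCutoff numeric; hits with e-value above this are discarded
#'   (inclusive boundary: `evalue <= evalueCutoff` is retained). Default
#'   1e-10.
#' @slot minIntervalSeparationBp integer; hits on the same scaffold whose
#'   query intervals overlap or lie within this many bp of each other are
#'   clustered into one putative gene interval before best-hit selection.
#' @export
setClass("HomologyConfig", slots = c(
  evalueCutoff = "numeric",
  minIntervalSeparationBp = "integer"
))

setValidity("HomologyConfig", function(object) {
  if (!is.finite(object@evalueCutoff) || object@evalueCutoff <= 0)
    return("evalueCutoff must be > 0")
  if (object@minIntervalSeparationBp < 0L)
    return("minIntervalSeparationBp must be >= 0")
  TRUE
})

#' @rdname HomologyConfig-class
#' @param evalueCutoff,minIntervalSeparationBp see slots.
#' @return a `HomologyConfig` object.
#' @export
homologyConfig <- function(evalueCutoff = 1e-10, minIntervalSeparationBp = 1L) {
  new("HomologyConfig", evalueCutoff = evalueCutoff,
      minIntervalSeparationBp = as.integer(minIntervalSeparationBp))
}

#' Chromosome-homology classification configuration
#'
#' @slot segmentThresholdPct numeric; a model chromosome holding strictly
#'   more than this percentage of a linkage group's placed homologs is
#'   called a homologous segment (default 10).
#' @slot highlightThresholdPct numeric; cells strictly above this are
#'   flagged "major" (default 30); cells between the two thresholds are
#'   "minor".
#' @export
setClass("ChromoMapConfig", slots = c(
  segmentThresholdPct = "numeric",
  highlightThresholdPct = "numeric"
))

setValidity("ChromoMapConfig", function(object) {
  if (!(object@segmentThresholdPct > 0 &&
        object@segmentThresholdPct < object@highlightThresholdPct &&
        object@highlightThresholdPct <= 100))
    return("need 0 < segmentThresholdPct < highlightThresholdPct <= 100")
  TRUE
})

#' @rdname ChromoMapConfig-class
#' @param segmentThresholdPct,highlightThresholdPct see slots.
#' @return a `ChromoMapConfig` object.
#' @export
chromoMapConfig <- function(segmentThresholdPct = 10,
                            highlightThresholdPct = 30) {
  new("ChromoMapConfig", segmentThresholdPct = segmentThresholdPct,
      highlightThresholdPct = highlightThresholdPct)
}

#' Synteny-detection configuration
#'
#' @slot minGenes integer >= 2; minimum genes per conserved block (two
#'   adjacent model-chromosome genes in one scaffold is the canonical rule).
#' @slot maxRankGap integer >= 0; number of missing adjacency ranks
#'   tolerated inside a run (0 = strictly adjacent genes).
#' @slot adjacencyUniverse `"ALL_ANNOTATED"` (adjacency ranks taken over the
#'   full model annotation) or `"HIT_ONLY"` (ranks densified over genes with
#'   at least one assignment anywhere, so unhit genes do not break runs).
#' @export
setClass("SyntenyConfig", slots = c(
  minGenes = "integer",
  maxRankGap = "integer",
  adjacencyUniverse = "character"
))

setValidity("SyntenyConfig", function(object) {
  if (object@minGenes < 2L) return("minGenes must be >= 2")
  if (object@maxRankGap < 0L) return("maxRankGap must be >= 0")
  if (!object@adjacencyUniverse %in% c("ALL_ANNOTATED", "HIT_ONLY"))
    return("adjacencyUniverse must be 'ALL_ANNOTATED' or 'HIT_ONLY'")
  TRUE
})

#' @rdname SyntenyConfig-class
#' @param minGenes,maxRankGap,adjacencyUniverse see slots.
#' @return a `SyntenyConfig` object.
#' @export
syntenyConfig <- function(minGenes = 2L, maxRankGap = 0L,
                          adjacencyUniverse = c("ALL_ANNOTATED", "HIT_ONLY")) {
  new("SyntenyConfig", minGenes = as.integer(minGenes),
      maxRankGap = as.integer(maxRankGap),
      adjacencyUniverse = match.arg(adjacencyUniverse))
}

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Anchored scaffold set
#'
#' Result of [buildEvidenceChains()]: one row per scaffold reached by at
#' least one complete marker -> BAC -> physical contig -> anchor sequence ->
#' scaffold chain, with status `ANCHORED` (single linkage group; position is
#' the median cM of its supporting markers) or `CONFLICT` (supported by more
#' than one linkage group and excluded from the anchored set under the
#' default policy). The full per-chain evidence is retained for audit.
#'
#' @slot scaffolds data.frame with columns `scaffold_id`, `linkage_group`,
#'   `position_cm`, `n_chains`, `status`.
#' @slot evidence data.frame of individual chains with columns
#'   `scaffold_id`, `marker_id`, `bac_id`, `contig_id`, `anchor_seq_id`,
#'   `anchor_seq_kind`, `linkage_group`, `position_cm`.
#' @export
setClass("AnchoredScaffoldSet", slots = c(
  scaffolds = "data.frame",
  evidence = "data.frame"
))

setValidity("AnchoredScaffoldSet", function(object) {
  need <- c("scaffold_id", "linkage_group", "position_cm", "n_chains", "status")
  if (!all(need %in% names(object@scaffolds)))
    return("scaffolds slot lacks required columns")
  if (anyDuplicated(object@scaffolds$scaffold_id))
    return("duplicate scaffold_id in anchored set")
  if (!all(object@scaffolds$status %in% c("ANCHORED", "CONFLICT")))
    return("status must be ANCHORED or CONFLICT")
  TRUE
})

#' Anchoring summary statistics
#'
#' Assembly-level summary of an anchoring run: scaffold counts, N50 values
#' (standard rule: largest length L such that scaffolds of length >= L sum
#' to at least half the total), total and anchored span, and the anchored
#' fraction of the assembly.
#'
#' @slot nScaffolds,nAnchored integer counts.
#' @slot n50Bp,n50AnchoredBp integer N50 values in bp.
#' @slot totalSpanBp,anchoredLengthBp numeric spans in bp.
#' @slot anchoredFraction numeric in `[0,1]` (0 for an empty assembly).
#' @export
setClass("AnchorStats", slots = c(
  nScaffolds = "integer",
  n50Bp = "numeric",
  totalSpanBp = "numeric",
  nAnchored = "integer",
  n50AnchoredBp = "numeric",
  anchoredLengthBp = "numeric",
  anchoredFraction = "numeric"
))

setValidity("AnchorStats", function(object) {
  if (object@nAnchored > object@nScaffolds)
    return("nAnchored cannot exceed nScaffolds")
  if (object@anchoredLengthBp > object@totalSpanBp + 1e-9)
    return("anchoredLengthBp cannot exceed totalSpanBp")
  if (object@anchoredFraction < 0 || object@anchoredFraction > 1)
    return("anchoredFraction must be in [0,1]")
  TRUE
})

#' Oxford-grid gene-sharing matrix
#'
#' Linkage-group x model-chromosome matrix of homologous-gene sharing. Cell
#' (LG, chr) holds the percentage of the LG's unique chromosome-placed
#' homologs located on that model chromosome; rows therefore sum to 100 (for
#' linkage groups with at least one placed homolog). Underlying unique-gene
#' counts and per-row denominators are retained at full precision; integer
#' rendering is applied only on export.
#'
#' @slot pct numeric matrix of percentages (full precision).
#' @slot counts integer matrix of unique placed homolog counts.
#' @slot denominators named integer vector, one per row.
#' @slot species character; model species label.
#' @export
setClass("HomologyMatrix", slots = c(
  pct = "matrix",
  counts = "matrix",
  denominators = "integer",
  species = "character"
))

setValidity("HomologyMatrix", function(object) {
  if (!identical(dim(object@pct), dim(object@counts)))
    return("pct and counts dimensions differ")
  if (length(object@denominators) != nrow(object@pct))
    return("one denominator per row required")
  if (any(object@pct < -1e-9 | object@pct > 100 + 1e-9))
    return("cells must lie in [0,100]")
  pos <- object@denominators > 0L
  if (any(pos)) {
    sums <- rowSums(object@pct[pos, , drop = FALSE])
    nz <- rowSums(object@pct[pos, , drop = FALSE] > 0)
    if (any(abs(sums - 100) > pmax(0.5 * nz, 1e-6)))
      return("rows with placed homologs must sum to 100 within rounding tolerance")
  }
  TRUE
})

#' Simulated comparative-genome bundle
#'
#' Everything one seeded run of the generator produces: the model
#' annotation, the rearranged target genome laid out on scaffolds, the
#' linkage-map/evidence tables, the hit table, and the ground truth (event
#' log and per-scaffold truth segments) that downstream validation compares
#' against.
#'
#' @slot config the [SimConfig-class] used.
#' @slot modelGenes model-species annotation (`species`, `gene_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `rank`).
#' @slot targetGenes target-genome gene layout (`gene_id`, `linkage_group`,
#'   `scaffold_id`, `start_bp`, `end_bp` within scaffold,
#'   `model_chromosome`, `model_rank`, `target_order`).
#' @slot scaffolds scaffold index (`scaffold_id`, `length_bp`, plus truth
#'   columns `linkage_group`, `offset_bp`).
#' @slot markers linkage-map marker table.
#' @slot bacContig,contigAnchors,seqScaffold evidence tables (BAC ->
#'   physical contig membership; contig -> anchor sequence; anchor
#'   sequence -> scaffold match).
#' @slot hits protein-alignment hit table (true + paralog + spurious hits).
#' @slot truthSegments per-scaffold maximal consecutive-rank runs on single
#'   model chromosomes (the ground truth for block detection).
#' @slot eventLog rearrangement event log.
#' @export
setClass("SynMapSim", slots = c(
  config = "SimConfig",
  modelGenes = "data.frame",
  targetGenes = "data.frame",
  scaffolds = "data.frame",
  markers = "data.frame",
  bacContig = "data.frame",
  contigAnchors = "data.frame",
  seqScaffold = "data.frame",
  hits = "data.frame",
  truthSegments = "data.frame",
  eventLog = "data.frame"
))

setValidity("SynMapSim", function(object) {
  nLost <- sum(object@eventLog$type == "loss")
  if (nrow(object@modelGenes) != nrow(object@targetGenes) + nLost)
    return("gene conservation violated: model genes != target genes + losses")
  if (anyDuplicated(object@targetGenes$gene_id))
    return("duplicate gene in target genome")
  TRUE
})
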