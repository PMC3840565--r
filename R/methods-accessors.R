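# Accessor and show() methods.

#' @rdname AnchoredScaffoldSet-class
#' @aliases anchoredScaffolds,AnchoredScaffoldSet-method
#' @export
setMethod("anchoredScaffolds", "AnchoredScaffoldSet", function(x) {
  x@scaffolds[x@scaffolds$status == "ANCHORED", , drop = FALSE]
})

#' @rdname AnchoredScaffoldSet-class
#' @aliases conflictedScaffolds,AnchoredScaffoldSet-method
#' @export
setMethod("conflictedScaffolds", "AnchoredScaffoldSet", function(x) {
  x@scaffolds[x@scaffolds$status == "CONFLICT", , drop = FALSE]
})

#' @rdname AnchoredScaffoldSet-class
#' @aliases evidenceChains,AnchoredScaffoldSet-method
#' @export
setMethod("evidenceChains", "AnchoredScaffoldSet", function(x) x@evidence)

setMethod("show", "AnchoredScaffoldSet", function(object) {
  n <- nrow(object@scaffolds)
  na <- sum(object@scaffolds$status == "ANCHORED")
  cat(sprintf("AnchoredScaffoldSet: %d scaffold(s) with evidence (%d anchored, %d conflicted)\n",
              n, na, n - na))
  cat(sprintf("  %d evidence chain(s); linkage groups: %s\n",
              nrow(object@evidence),
              paste(utils::head(.naturalSort(unique(object@scaffolds$linkage_group[
                object@scaffolds$status == "ANCHORED"])), 8L), collapse = ", ")))
})

#' @rdname AnchorStats-class
#' @aliases anchoredPercent,AnchorStats-method
#' @export
setMethod("anchoredPercent", "AnchorStats", function(x) {
  roundHalfUp(100 * x@anchoredFraction)
})

#' Coerce anchoring statistics to a one-row data.frame
#'
#' @param x an [AnchorStats-class] object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return a one-row data.frame.
#' @export
as.data.frame.AnchorStats <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(n_scaffolds_total = x@nScaffolds,
             n50_scaffolds_bp = x@n50Bp,
             total_span_bp = x@totalSpanBp,
             n_anchored = x@nAnchored,
             n50_anchored_bp = x@n50AnchoredBp,
             anchored_length_bp = x@anchoredLengthBp,
             anchored_fraction = x@anchoredFraction,
             anchored_percent = anchoredPercent(x))
}

setMethod("show", "AnchorStats", function(object) {
  cat("AnchorStats\n")
  cat(sprintf("  scaffolds: %d (N50 %s bp, span %s bp)\n", object@nScaffolds,
              format(object@n50Bp, big.mark = ","),
              format(object@totalSpanBp, big.mark = ",")))
  cat(sprintf("  anchored:  %d (N50 %s bp, span %s bp, %.1f%% of assembly)\n",
              object@nAnchored, format(object@n50AnchoredBp, big.mark = ","),
              format(object@anchoredLengthBp, big.mark = ","),
              100 * object@anchoredFraction))
})

#' @rdname HomologyMatrix-class
#' @aliases sharingPct,HomologyMatrix-method
#' @export
setMethod("sharingPct", "HomologyMatrix", function(x) x@pct)

#' @rdname HomologyMatrix-class
#' @aliases sharingCounts,HomologyMatrix-method
#' @export
setMethod("sharingCounts", "HomologyMatrix", function(x) x@counts)

#' @rdname HomologyMatrix-class
#' @aliases lgDenominators,HomologyMatrix-method
#' @export
setMethod("lgDenominators", "HomologyMatrix", function(x) x@denominators)

setMethod("show", "HomologyMatrix", function(object) {
  cat(sprintf("HomologyMatrix (%s): %d linkage group(s) x %d chromosome(s), %d placed homolog(s)\n",
              object@species, nrow(object@pct), ncol(object@pct),
              sum(object@denominators)))
  k <- min(nrow(object@pct), 6L)
  if (k > 0L)
    print(roundHalfUp(object@pct[seq_len(k), , drop = FALSE]))
  if (nrow(object@pct) > k) cat("  ...\n")
})

#' @rdname SynMapSim-class
#' @aliases modelAnnotation,SynMapSim-method
#' @export
setMethod("modelAnnotation", "SynMapSim", function(x) x@modelGenes)

#' @rdname SynMapSim-class
#' @aliases targetGenes,SynMapSim-method
#' @export
setMethod("targetGenes", "SynMapSim", function(x) x@targetGenes)

#' @rdname SynMapSim-class
#' @aliases scaffoldIndex,SynMapSim-method
#' @export
setMethod("scaffoldIndex", "SynMapSim", function(x) x@scaffolds)

#' @rdname SynMapSim-class
#' @aliases markerTable,SynMapSim-method
#' @export
setMethod("markerTable", "SynMapSim", function(x) x@markers)

#' @rdname SynMapSim-class
#' @aliases hitTable,SynMapSim-method
#' @export
setMethod("hitTable", "SynMapSim", function(x) x@hits)

#' @rdname SynMapSim-class
#' @aliases truthSegments,SynMapSim-method
#' @export
setMethod("truthSegments", "SynMapSim", function(x) x@truthSegments)

#' @rdname SynMapSim-class
#' @aliases eventLog,SynMapSim-method
#' @export
setMethod("eventLog", "SynMapSim", function(x) x@eventLog)

#' @rdname SynMapSim-class
#' @aliases evidenceTables,SynMapSim-method
#' @export
setMethod("evidenceTables", "SynMapSim", function(x) {
  list(bacContig = x@bacContig, contigAnchors = x@contigAnchors,
       seqScaffold = x@seqScaffold)
})

#' @rdname SynMapSim-class
#' @aliases simulationConfig,SynMapSim-method
#' @export
setMethod("simulationConfig", "SynMapSim", function(x) x@config)

setMethod("show", "SynMapSim", function(object) {
  cat("SynMapSim (seeded comparative-genome simulation)\n")
  cat(sprintf("  model:    %d gene(s) on %d chromosome(s)\n",
              nrow(object@modelGenes), length(unique(object@modelGenes$chromosome))))
  cat(sprintf("  target:   %d gene(s) on %d linkage group(s), %d scaffold(s)\n",
              nrow(object@targetGenes),
              length(unique(object@targetGenes$linkage_group)),
              nrow(object@scaffolds)))
  cat(sprintf("  markers:  %d; hits: %d; truth segments: %d; events: %d\n",
              nrow(object@markers), nrow(object@hits),
              nrow(object@truthSegments),
              sum(object@eventLog$type != "loss")))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  seed %d; %d chromosomes x %d genes (%d+%d bp layout)\n",
              object@seed, object@nChromosomes, object@genesPerChromosome,
              object@geneLengthBp, object@intergenicBp))
  cat(sprintf("  events: %d fusion, %d fission, %d inversion, %d translocation; loss %.2f\n",
              object@nFusions, object@nFissions, object@nInversions,
              object@nTranslocations, object@geneLossRate))
  cat(sprintf("  noise: spurious %.2f, paralog %.2f; N50 target %d bp; %g markers/Mb @ %g cM bins\n",
              object@spuriousHitRate, object@paralogRate,
              object@scaffoldN50Target, object@markerDensityPerMb,
              object@mapResolutionCm))
})
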