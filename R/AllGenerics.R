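# Accessor generics for the package's S4 containers.

#' @rdname AnchoredScaffoldSet-class
#' @param x an object.
#' @export
setGeneric("anchoredScaffolds", function(x) standardGeneric("anchoredScaffolds"))

#' @rdname AnchoredScaffoldSet-class
#' @export
setGeneric("conflictedScaffolds", function(x) standardGeneric("conflictedScaffolds"))

#' @rdname AnchoredScaffoldSet-class
#' @export
setGeneric("evidenceChains", function(x) standardGeneric("evidenceChains"))

#' @rdname HomologyMatrix-class
#' @param x an object.
#' @export
setGeneric("sharingPct", function(x) standardGeneric("sharingPct"))

#' @rdname HomologyMatrix-class
#' @export
setGeneric("sharingCounts", function(x) standardGeneric("sharingCounts"))

#' @rdname HomologyMatrix-class
#' @export
setGeneric("lgDenominators", function(x) standardGeneric("lgDenominators"))

#' @rdname AnchorStats-class
#' @param x an object.
#' @export
setGeneric("anchoredPercent", function(x) standardGeneric("anchoredPercent"))

#' @rdname SynMapSim-class
#' @param x an object.
#' @export
setGeneric("modelAnnotation", function(x) standardGeneric("modelAnnotation"))

#' @rdname SynMapSim-class
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname SynMapSim-class
#' @export
setGeneric("scaffoldIndex", function(x) standardGeneric("scaffoldIndex"))

#' @rdname SynMapSim-class
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname SynMapSim-class
#' @export
setGeneric("hitTable", function(x) standardGeneric("hitTable"))

#' @rdname SynMapSim-class
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))

#' @rdname SynMapSim-class
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname SynMapSim-class
#' @export
setGeneric("evidenceTables", function(x) standardGeneric("evidenceTables"))

#' @rdname SynMapSim-class
#' @export
setGeneric("simulationConfig", function(x) standardGeneric("simulationConfig"))
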