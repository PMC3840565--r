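# Bundled reference summary tables from the published channel
# catfish--zebrafish whole-genome comparison (display precision: spans in
# Kb, integer means). The underlying raw data are unpublished; these
# packaged summaries support aggregation checks, not re-derivation.

#' Bundled catfish--zebrafish reference summaries
#'
#' `referenceBlockSummary()` returns the published per-linkage-group
#' conserved-synteny summary for the channel catfish vs zebrafish
#' comparison (29 linkage groups; spans in Kb at display precision).
#' `referenceAnchoringSummary()` returns the published anchored-assembly
#' statistics (scaffold counts, N50s, spans in Mb) as a named list.
#'
#' @return `referenceBlockSummary()`: data.frame with columns
#'   `linkage_group`, `total_span_kb`, `n_blocks`, `mean_span_kb`,
#'   `max_span_kb`, `n50_span_kb`, `n_genes`, `mean_genes_per_block`.
#' @examples
#' aggregateBlockSummary(referenceBlockSummary())
#' @export
referenceBlockSummary <- function() {
  f <- system.file("extdata", "catfish_zebrafish_block_summary.tsv",
                   package = "synmapr", mustWork = TRUE)
  utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname referenceBlockSummary
#' @export
referenceAnchoringSummary <- function() {
  f <- system.file("extdata", "catfish_anchoring_summary.tsv",
                   package = "synmapr", mustWork = TRUE)
  df <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.list(as.numeric(df$value)), df$statistic)
}
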