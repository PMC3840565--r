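# Conserved synteny block detection: within each (scaffold, model
# chromosome) pair, genes are sorted by model rank and greedily partitioned
# into maximal runs of near-consecutive ranks; runs with at least two genes
# are conserved blocks. Per-linkage-group summary statistics (counts,
# spans, N50) and a truth-comparison harness complete the module.

#' Detect conserved syntenic blocks
#'
#' Within each (scaffold, model chromosome) pair, the unique assigned
#' placed genes are sorted by adjacency rank and partitioned into maximal
#' runs where successive rank differences are at most `1 + maxRankGap`.
#' Runs with at least `minGenes` genes become blocks. Under
#' `ALL_ANNOTATED` the adjacency rank is the model annotation rank; under
#' `HIT_ONLY`, ranks are densified over the genes with at least one
#' assignment anywhere, so unhit annotation genes do not break runs.
#' Assignments to `UNPLACED` genes are skipped with a logged count; blocks
#' never span two scaffolds. Spans are measured in model-species
#' coordinates (first gene start to last gene end).
#'
#' @param lgAssignments assignments carrying linkage groups
#'   ([homologsPerLinkageGroup()]).
#' @param annotation model gene annotation.
#' @param config a [SyntenyConfig-class].
#' @return data.frame of blocks: `block_id`, `scaffold_id`,
#'   `linkage_group`, `model_chromosome`, `gene_ids` (semicolon-joined in
#'   rank order), `n_genes`, `model_start_bp`, `model_end_bp`, `span_bp`.
#' @export
detectSyntenyBlocks <- function(lgAssignments, annotation,
                                config = syntenyConfig()) {
  stopifnot(is(config, "SyntenyConfig"))
  .checkColumns(lgAssignments, c("scaffold_id", "linkage_group", "gene_id",
                                 "chromosome", "rank", "placed"),
                "LG assignments")
  nUnplaced <- sum(!lgAssignments$placed)
  if (nUnplaced)
    .msgf("detectSyntenyBlocks: skipping %d assignment(s) to unplaced genes",
          nUnplaced)
  a <- lgAssignments[lgAssignments$placed, , drop = FALSE]
  if (!nrow(a)) return(.emptyBlocks())

  startOf <- stats::setNames(annotation$start_bp, annotation$gene_id)
  endOf <- stats::setNames(annotation$end_bp, annotation$gene_id)
  if (config@adjacencyUniverse == "HIT_ONLY") {
    hitGenes <- annotation[annotation$gene_id %in% unique(a$gene_id) &
                             annotation$chromosome != UNPLACED, , drop = FALSE]
    hitGenes <- assignGeneRanks(hitGenes)
    rankOf <- stats::setNames(hitGenes$rank, hitGenes$gene_id)
  } else {
    rankOf <- stats::setNames(annotation$rank, annotation$gene_id)
  }
  a$adjacency_rank <- unname(rankOf[a$gene_id])

  u <- unique(a[, c("scaffold_id", "linkage_group", "chromosome", "gene_id",
                    "adjacency_rank")])
  key <- paste(u$scaffold_id, u$chromosome, sep = "\r")
  maxDiff <- 1L + config@maxRankGap
  pieces <- lapply(split(seq_len(nrow(u)), key), function(rows) {
    g <- u[rows, , drop = FALSE]
    g <- g[order(g$adjacency_rank), , drop = FALSE]
    runid <- cumsum(c(1L, diff(g$adjacency_rank) > maxDiff))
    runs <- split(seq_len(nrow(g)), runid)
    runs <- runs[vapply(runs, length, integer(1)) >= config@minGenes]
    if (!length(runs)) return(NULL)
    do.call(rbind, lapply(seq_along(runs), function(ri) {
      gg <- g[runs[[ri]], , drop = FALSE]
      s <- min(startOf[gg$gene_id]); e <- max(endOf[gg$gene_id])
      data.frame(
        block_id = sprintf("%s|%s|%d", gg$scaffold_id[[1L]],
                           gg$chromosome[[1L]], ri),
        scaffold_id = gg$scaffold_id[[1L]],
        linkage_group = gg$linkage_group[[1L]],
        model_chromosome = gg$chromosome[[1L]],
        gene_ids = paste(gg$gene_id, collapse = ";"),
        n_genes = nrow(gg),
        model_start_bp = as.integer(s),
        model_end_bp = as.integer(e),
        span_bp = as.integer(e - s + 1),
        stringsAsFactors = FALSE)
    }))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(.emptyBlocks())
  out <- do.call(rbind, pieces)
  out <- out[order(out$scaffold_id, out$model_chromosome, out$model_start_bp,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyBlocks <- function() {
  data.frame(block_id = character(), scaffold_id = character(),
             linkage_group = character(), model_chromosome = character(),
             gene_ids = character(), n_genes = integer(),
             model_start_bp = integer(), model_end_bp = integer(),
             span_bp = integer(), stringsAsFactors = FALSE)
}

#' Summarize conserved blocks per linkage group
#'
#' Per-linkage-group statistics plus a `Total` row: block count, total /
#' mean / maximum span, span N50 (standard rule over block spans), gene
#' count and mean genes per block. Means are returned unrounded; the
#' display convention (spans to the nearest Kb, genes per block to the
#' nearest integer) is applied by [formatBlockSummary()]. The totals row's
#' counts, spans and gene numbers are exact column sums and its means are
#' the corresponding ratios.
#'
#' @param blocks data.frame from [detectSyntenyBlocks()].
#' @return summary data.frame with columns `linkage_group`, `n_blocks`,
#'   `total_span_bp`, `mean_span_bp`, `max_span_bp`, `n50_span_bp`,
#'   `n_genes`, `mean_genes_per_block`.
#' @export
summarizeBlocks <- function(blocks) {
  if (!nrow(blocks)) {
    return(data.frame(linkage_group = "Total", n_blocks = 0L,
                      total_span_bp = 0, mean_span_bp = 0, max_span_bp = 0,
                      n50_span_bp = 0, n_genes = 0L, mean_genes_per_block = 0,
                      stringsAsFactors = FALSE))
  }
  .checkColumns(blocks, c("linkage_group", "span_bp", "n_genes"), "blocks")
  oneRow <- function(lg, b) {
    data.frame(linkage_group = lg,
               n_blocks = nrow(b),
               total_span_bp = sum(as.numeric(b$span_bp)),
               mean_span_bp = mean(b$span_bp),
               max_span_bp = max(b$span_bp),
               n50_span_bp = computeN50(b$span_bp),
               n_genes = sum(b$n_genes),
               mean_genes_per_block = mean(b$n_genes),
               stringsAsFactors = FALSE)
  }
  lgs <- .naturalSort(unique(blocks$linkage_group))
  out <- do.call(rbind, lapply(lgs, function(lg) {
    oneRow(lg, blocks[blocks$linkage_group == lg, , drop = FALSE])
  }))
  out <- rbind(out, oneRow("Total", blocks))
  rownames(out) <- NULL
  out
}

#' @rdname summarizeBlocks
#' @param summary data.frame from `summarizeBlocks()`.
#' @return `formatBlockSummary()`: display version with spans in Kb
#'   (rounded half-up to integers) and genes per block rounded to the
#'   nearest integer.
#' @export
formatBlockSummary <- function(summary) {
  data.frame(linkage_group = summary$linkage_group,
             total_span_kb = roundHalfUp(summary$total_span_bp / 1000),
             n_blocks = summary$n_blocks,
             mean_span_kb = roundHalfUp(summary$mean_span_bp / 1000),
             max_span_kb = roundHalfUp(summary$max_span_bp / 1000),
             n50_span_kb = roundHalfUp(summary$n50_span_bp / 1000),
             n_genes = summary$n_genes,
             mean_genes_per_block = roundHalfUp(summary$mean_genes_per_block),
             stringsAsFactors = FALSE)
}

#' Aggregate a per-linkage-group display table
#'
#' Recomputes the totals and derived display means from per-linkage-group
#' rows of a formatted block summary (spans in Kb): total blocks, total
#' span, total genes, mean span per block and mean genes per block (both
#' rounded half-up, matching the display convention), and the range of
#' per-LG block counts.
#'
#' @param perLG data.frame with columns `total_span_kb`, `n_blocks`,
#'   `n_genes` (one row per linkage group, no totals row).
#' @return named list of the aggregates.
#' @export
aggregateBlockSummary <- function(perLG) {
  .checkColumns(perLG, c("total_span_kb", "n_blocks", "n_genes"),
                "per-LG summary")
  nb <- sum(perLG$n_blocks)
  sp <- sum(as.numeric(perLG$total_span_kb))
  ng <- sum(perLG$n_genes)
  list(n_blocks = nb,
       total_span_kb = sp,
       n_genes = ng,
       mean_span_kb = roundHalfUp(sp / nb),
       mean_genes_per_block = roundHalfUp(ng / nb),
       min_blocks_per_lg = min(perLG$n_blocks),
       max_blocks_per_lg = max(perLG$n_blocks))
}

#' Compare detected blocks against ground-truth segments
#'
#' A detected block matches a truth segment when scaffold, model chromosome
#' and gene set are identical. Precision is matched / detected (1 when
#' nothing was detected), recall is matched eligible truth segments /
#' truth segments with at least `minGenes` genes (1 when none are
#' eligible), and the exact-match fraction is the Jaccard index of the two
#' block-key sets.
#'
#' @param blocks data.frame from [detectSyntenyBlocks()].
#' @param truth truth-segment data.frame (`scaffold_id`,
#'   `model_chromosome`, `gene_ids`, `n_genes`).
#' @param minGenes integer; truth segments below this size are not
#'   expected to be detected.
#' @return named list `precision`, `recall`, `exact_match_fraction`,
#'   `n_detected`, `n_truth`.
#' @export
compareToTruth <- function(blocks, truth, minGenes = 2L) {
  keyOf <- function(scaf, chrom, genes) {
    paste(scaf, chrom,
          vapply(strsplit(genes, ";", fixed = TRUE),
                 function(g) paste(sort(g), collapse = ";"), character(1)),
          sep = "\r")
  }
  det <- if (nrow(blocks))
    unique(keyOf(blocks$scaffold_id, blocks$model_chromosome,
                 blocks$gene_ids)) else character()
  eligible <- truth[truth$n_genes >= minGenes, , drop = FALSE]
  tru <- if (nrow(eligible))
    unique(keyOf(eligible$scaffold_id, eligible$model_chromosome,
                 eligible$gene_ids)) else character()
  nMatch <- length(intersect(det, tru))
  uni <- length(union(det, tru))
  list(precision = if (length(det)) nMatch / length(det) else 1,
       recall = if (length(tru)) nMatch / length(tru) else 1,
       exact_match_fraction = if (uni) nMatch / uni else 1,
       n_detected = length(det),
       n_truth = length(tru))
}
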