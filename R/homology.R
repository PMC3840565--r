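# Homolog identification: e-value filtering of alignment hits, best-hit
# interval clustering on scaffolds, and per-linkage-group unique-homolog
# accounting (all homologs vs chromosome-placed homologs).

#' Filter hits by e-value
#'
#' Retains exactly the hits with `evalue <= evalueCutoff` (inclusive
#' boundary), preserving input order. Idempotent.
#'
#' @param hits hit data.frame ([readHitTable()]).
#' @param config a [HomologyConfig-class] (default cutoff 1e-10).
#' @return the filtered data.frame.
#' @export
filterHits <- function(hits, config = homologyConfig()) {
  stopifnot(is(config, "HomologyConfig"))
  .checkColumns(hits, c("evalue"), "hits")
  out <- hits[hits$evalue <= config@evalueCutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster hits into intervals and keep the best hit per interval
#'
#' Hits on the same scaffold whose query intervals overlap or lie within
#' `minIntervalSeparationBp` of each other are clustered into one putative
#' gene interval. Each interval keeps the single best hit by highest
#' bitscore, then lowest e-value, then lexicographically smallest subject
#' id, yielding one homolog assignment per interval. The result is
#' independent of input hit order.
#'
#' @param hits filtered hit data.frame.
#' @param annotation model gene annotation ([readGeneAnnotation()]).
#' @param config a [HomologyConfig-class].
#' @param strict logical; a hit whose subject is absent from the annotation
#'   is an integrity error when `TRUE` (default), else dropped with a
#'   warning.
#' @return assignment data.frame: `scaffold_id`, `query_start`,
#'   `query_end` (the clustered interval), `gene_id`, `species`,
#'   `chromosome`, `gene_start_bp`, `gene_end_bp`, `rank`, `evalue`,
#'   `bitscore`.
#' @export
assignBestHits <- function(hits, annotation, config = homologyConfig(),
                           strict = TRUE) {
  stopifnot(is(config, "HomologyConfig"))
  .checkColumns(hits, c("query_id", "query_start", "query_end", "subject_id",
                        "evalue", "bitscore"), "hits")
  .checkColumns(annotation, c("species", "gene_id", "chromosome", "start_bp",
                              "end_bp", "rank"), "annotation")
  idx <- match(hits$subject_id, annotation$gene_id)
  if (anyNA(idx)) {
    missing <- unique(hits$subject_id[is.na(idx)])
    if (strict)
      .stopf("integrity error: hit subject '%s' not in annotation",
             missing[[1L]])
    .warnf("dropping %d hit(s) to %d subject(s) absent from annotation",
           sum(is.na(idx)), length(missing))
    hits <- hits[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!nrow(hits)) return(.emptyAssignments())
  # canonical order makes clustering and tie-breaking permutation-invariant
  o <- order(hits$query_id, hits$query_start, hits$query_end,
             hits$subject_id, method = "radix")
  hits <- hits[o, , drop = FALSE]
  idx <- idx[o]
  sep <- config@minIntervalSeparationBp

  pieces <- lapply(split(seq_len(nrow(hits)), hits$query_id), function(rows) {
    h <- hits[rows, , drop = FALSE]
    a <- idx[rows]
    # new cluster when a hit starts beyond the running max end + separation
    runEnd <- cummax(h$query_end)
    newClust <- c(TRUE, h$query_start[-1L] > runEnd[-length(runEnd)] + sep)
    cl <- cumsum(newClust)
    do.call(rbind, lapply(split(seq_along(cl), cl), function(j) {
      hh <- h[j, , drop = FALSE]
      win <- order(-hh$bitscore, hh$evalue, hh$subject_id)[[1L]]
      ann <- annotation[a[j][win], , drop = FALSE]
      data.frame(scaffold_id = hh$query_id[[1L]],
                 query_start = min(hh$query_start),
                 query_end = max(hh$query_end),
                 gene_id = ann$gene_id,
                 species = ann$species,
                 chromosome = ann$chromosome,
                 gene_start_bp = ann$start_bp,
                 gene_end_bp = ann$end_bp,
                 rank = ann$rank,
                 evalue = hh$evalue[[win]],
                 bitscore = hh$bitscore[[win]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$scaffold_id, out$query_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyAssignments <- function() {
  data.frame(scaffold_id = character(), query_start = integer(),
             query_end = integer(), gene_id = character(),
             species = character(), chromosome = character(),
             gene_start_bp = integer(), gene_end_bp = integer(),
             rank = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Attach linkage groups to homolog assignments
#'
#' Joins assignments with the anchored scaffold set; assignments on
#' scaffolds that are not anchored (absent or conflicted) are dropped with
#' a logged count. Each retained assignment carries its linkage group, map
#' position, and a `placed` flag (`FALSE` for genes on the `UNPLACED`
#' chromosome).
#'
#' @param assignments from [assignBestHits()].
#' @param anchored an [AnchoredScaffoldSet-class] or a data.frame with
#'   `scaffold_id`, `linkage_group`, `position_cm`.
#' @return the assignments with `linkage_group`, `position_cm` and
#'   `placed` columns.
#' @export
homologsPerLinkageGroup <- function(assignments, anchored) {
  anc <- if (is(anchored, "AnchoredScaffoldSet")) anchoredScaffolds(anchored)
         else anchored
  .checkColumns(anc, c("scaffold_id", "linkage_group", "position_cm"),
                "anchored scaffolds")
  i <- match(assignments$scaffold_id, anc$scaffold_id)
  nDropped <- sum(is.na(i))
  if (nDropped)
    .msgf("homologsPerLinkageGroup: dropping %d assignment(s) on unanchored scaffolds",
          nDropped)
  out <- assignments[!is.na(i), , drop = FALSE]
  i <- i[!is.na(i)]
  out$linkage_group <- anc$linkage_group[i]
  out$position_cm <- anc$position_cm[i]
  out$placed <- out$chromosome != UNPLACED
  rownames(out) <- NULL
  out
}

#' Count unique homologs per linkage group
#'
#' For each linkage group, counts unique subject genes twice: all homologs,
#' and only those placed on a model chromosome (`UNPLACED` excluded) --
#' the paired accounting used for per-species homolog summaries. A gene hit
#' by scaffolds on two linkage groups is counted in both; the size of that
#' overlap is reported as an attribute and logged.
#'
#' @param lgAssignments from [homologsPerLinkageGroup()].
#' @return data.frame `linkage_group`, `n_homologs`, `n_placed`, with
#'   attributes `total_unique` / `total_unique_placed` (genome-wide unique
#'   counts) and `multi_lg_genes` (genes counted in more than one LG).
#' @export
countHomologsPerLG <- function(lgAssignments) {
  .checkColumns(lgAssignments, c("linkage_group", "gene_id", "placed"),
                "LG assignments")
  u <- unique(lgAssignments[, c("linkage_group", "gene_id", "placed")])
  lgs <- .naturalSort(unique(u$linkage_group))
  out <- data.frame(
    linkage_group = lgs,
    n_homologs = vapply(lgs, function(g) sum(u$linkage_group == g),
                        integer(1)),
    n_placed = vapply(lgs, function(g) sum(u$linkage_group == g & u$placed),
                      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  multi <- sum(table(unique(u[, c("linkage_group", "gene_id")])$gene_id) > 1L)
  if (multi)
    .msgf("countHomologsPerLG: %d gene(s) hit from more than one linkage group (counted in each)",
          multi)
  attr(out, "total_unique") <- length(unique(u$gene_id))
  attr(out, "total_unique_placed") <- length(unique(u$gene_id[u$placed]))
  attr(out, "multi_lg_genes") <- multi
  out
}
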