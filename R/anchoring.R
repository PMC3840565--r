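# Scaffold anchoring: walk the five-step evidence chain
# marker -> source BAC -> physical-map contig -> anchor sequence (BES or
# PMCSS) -> scaffold, place each reachable scaffold on a linkage group, and
# summarize the anchored assembly.

#' Assembly N50
#'
#' Standard rule: the largest length L such that elements of length >= L
#' together cover at least half the total length. Ties in the cumulative
#' sum resolve to the first length reaching half-total in descending order.
#'
#' @param lengths numeric vector of element lengths.
#' @return the N50 (0 for an empty vector).
#' @examples
#' computeN50(c(5, 4, 3, 2, 1))  # 4
#' @export
computeN50 <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[[which(cumsum(s) >= sum(s) / 2)[[1L]]]]
}

#' Build scaffold-anchoring evidence chains
#'
#' A scaffold is anchored if at least one complete chain
#' marker -> BAC -> physical contig -> anchor sequence -> scaffold exists.
#' A scaffold supported by markers at several cM positions on one linkage
#' group takes the median position of its distinct supporting markers. A
#' scaffold supported by more than one linkage group is flagged `CONFLICT`:
#' under the default `"drop"` policy it is excluded from the anchored set
#' (retained in the result for inspection); under `"best-support"` the
#' linkage group with the most chains wins, with ties still dropped.
#'
#' @param markers linkage-map data.frame ([readLinkageMap()]).
#' @param bacToContig data.frame `bac_id`, `contig_id`.
#' @param contigAnchorSeqs data.frame `contig_id`, `anchor_seq_id`,
#'   `anchor_seq_kind`.
#' @param seqToScaffold data.frame `anchor_seq_id`, `scaffold_id`.
#' @param scaffolds optional scaffold index; in strict mode every scaffold
#'   referenced by the match table must exist in it.
#' @param strict logical; dangling id references are integrity errors
#'   naming the id when `TRUE` (default).
#' @param conflictPolicy `"drop"` (default) or `"best-support"`.
#' @return an [AnchoredScaffoldSet-class].
#' @export
buildEvidenceChains <- function(markers, bacToContig, contigAnchorSeqs,
                                seqToScaffold, scaffolds = NULL,
                                strict = TRUE,
                                conflictPolicy = c("drop", "best-support")) {
  conflictPolicy <- match.arg(conflictPolicy)
  .checkColumns(markers, c("marker_id", "linkage_group", "position_cm",
                           "source_bac_id"), "markers")
  .checkColumns(bacToContig, c("bac_id", "contig_id"), "bacToContig")
  .checkColumns(contigAnchorSeqs, c("contig_id", "anchor_seq_id",
                                    "anchor_seq_kind"), "contigAnchorSeqs")
  .checkColumns(seqToScaffold, c("anchor_seq_id", "scaffold_id"),
                "seqToScaffold")
  if (!is.null(scaffolds)) {
    dangling <- setdiff(seqToScaffold$scaffold_id, scaffolds$scaffold_id)
    if (length(dangling)) {
      if (strict)
        .stopf("integrity error: match table references unknown scaffold '%s'",
               dangling[[1L]])
      .warnf("dropping matches to %d unknown scaffold(s)", length(dangling))
      seqToScaffold <- seqToScaffold[
        !seqToScaffold$scaffold_id %in% dangling, , drop = FALSE]
    }
  }

  chains <- merge(markers, bacToContig,
                  by.x = "source_bac_id", by.y = "bac_id")
  chains <- merge(chains, contigAnchorSeqs, by = "contig_id")
  chains <- merge(chains, seqToScaffold, by = "anchor_seq_id")
  chains <- data.frame(
    scaffold_id = chains$scaffold_id,
    marker_id = chains$marker_id,
    bac_id = chains$source_bac_id,
    contig_id = chains$contig_id,
    anchor_seq_id = chains$anchor_seq_id,
    anchor_seq_kind = chains$anchor_seq_kind,
    linkage_group = chains$linkage_group,
    position_cm = chains$position_cm,
    stringsAsFactors = FALSE)
  chains <- chains[order(chains$scaffold_id, chains$marker_id,
                         chains$anchor_seq_id, method = "radix"), ,
                   drop = FALSE]
  rownames(chains) <- NULL

  if (!nrow(chains)) {
    return(new("AnchoredScaffoldSet",
               scaffolds = data.frame(scaffold_id = character(),
                                      linkage_group = character(),
                                      position_cm = numeric(),
                                      n_chains = integer(),
                                      status = character(),
                                      stringsAsFactors = FALSE),
               evidence = chains))
  }

  perScaffold <- lapply(split(chains, chains$scaffold_id), function(ch) {
    lgs <- unique(ch$linkage_group)
    status <- "ANCHORED"
    if (length(lgs) > 1L) {
      if (conflictPolicy == "best-support") {
        support <- sort(table(ch$linkage_group), decreasing = TRUE)
        if (length(support) > 1L && support[[1L]] == support[[2L]]) {
          status <- "CONFLICT"
        } else {
          ch <- ch[ch$linkage_group == names(support)[[1L]], , drop = FALSE]
          lgs <- names(support)[[1L]]
        }
      } else {
        status <- "CONFLICT"
      }
    }
    mk <- ch[!duplicated(ch$marker_id), , drop = FALSE]
    data.frame(scaffold_id = ch$scaffold_id[[1L]],
               linkage_group = if (status == "ANCHORED") lgs[[1L]] else
                 paste(.naturalSort(unique(ch$linkage_group)), collapse = ";"),
               position_cm = if (status == "ANCHORED")
                 stats::median(mk$position_cm) else NA_real_,
               n_chains = nrow(ch),
               status = status,
               stringsAsFactors = FALSE)
  })
  scafdf <- do.call(rbind, perScaffold)
  rownames(scafdf) <- NULL
  nConf <- sum(scafdf$status == "CONFLICT")
  if (nConf)
    .msgf("buildEvidenceChains: %d scaffold(s) with multi-linkage-group support excluded as CONFLICT",
          nConf)
  new("AnchoredScaffoldSet", scaffolds = scafdf, evidence = chains)
}

#' Summarize an anchoring run
#'
#' Computes assembly statistics over all scaffolds and over the anchored
#' subset: counts, N50 ([computeN50()]), total spans and the anchored
#' fraction of the assembly length. An empty scaffold set yields an all-zero
#' summary.
#'
#' @param scaffolds scaffold index data.frame (`scaffold_id`, `length_bp`).
#' @param anchored an [AnchoredScaffoldSet-class], a data.frame with a
#'   `scaffold_id` column, or a character vector of anchored scaffold ids.
#' @return an [AnchorStats-class].
#' @export
computeAnchorStats <- function(scaffolds, anchored) {
  .checkColumns(scaffolds, c("scaffold_id", "length_bp"), "scaffold index")
  ids <- if (is(anchored, "AnchoredScaffoldSet"))
    anchoredScaffolds(anchored)$scaffold_id
  else if (is.data.frame(anchored)) anchored$scaffold_id
  else as.character(anchored)
  unknown <- setdiff(ids, scaffolds$scaffold_id)
  if (length(unknown))
    .stopf("anchored set references unknown scaffold '%s'", unknown[[1L]])
  lens <- as.numeric(scaffolds$length_bp)
  aLens <- lens[scaffolds$scaffold_id %in% ids]
  total <- sum(lens)
  new("AnchorStats",
      nScaffolds = nrow(scaffolds),
      n50Bp = computeN50(lens),
      totalSpanBp = total,
      nAnchored = length(unique(ids)),
      n50AnchoredBp = computeN50(aLens),
      anchoredLengthBp = sum(aLens),
      anchoredFraction = if (total > 0) sum(aLens) / total else 0)
}
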