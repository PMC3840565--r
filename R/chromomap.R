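# Oxford-grid construction and homologous-chromosome classification: the
# linkage-group x model-chromosome gene-sharing percentage matrix, the
# >10% segment / >30% major-cell rule, and fusion/fission pattern calls
# from the two directions of the grid.

#' Build the Oxford-grid gene-sharing matrix
#'
#' Cell (LG, chr) is 100 x (unique placed homologs of the LG on that model
#' chromosome) / (unique placed homologs of the LG). Only chromosome-placed
#' homologs enter the denominator; `UNPLACED` genes are excluded. Full
#' precision is retained internally; integer rendering happens on export.
#'
#' @param lgAssignments from [homologsPerLinkageGroup()].
#' @param species model species label.
#' @param allLGs optional character vector of linkage groups that must
#'   appear as rows; LGs without placed homologs become all-zero rows with
#'   a warning.
#' @return a [HomologyMatrix-class].
#' @export
buildHomologyMatrix <- function(lgAssignments, species = "model",
                                allLGs = NULL) {
  .checkColumns(lgAssignments, c("linkage_group", "gene_id", "chromosome",
                                 "placed"), "LG assignments")
  u <- unique(lgAssignments[lgAssignments$placed,
                            c("linkage_group", "gene_id", "chromosome")])
  lgs <- .naturalSort(unique(c(u$linkage_group, allLGs)))
  chrs <- .naturalSort(unique(u$chromosome))
  counts <- matrix(0L, nrow = length(lgs), ncol = length(chrs),
                   dimnames = list(lgs, chrs))
  if (nrow(u)) {
    tab <- table(factor(u$linkage_group, levels = lgs),
                 factor(u$chromosome, levels = chrs))
    counts[] <- as.integer(tab)
  }
  denom <- as.integer(rowSums(counts))
  names(denom) <- lgs
  if (any(denom == 0L))
    .warnf("buildHomologyMatrix: %d linkage group(s) without placed homologs (empty rows)",
           sum(denom == 0L))
  pct <- counts * 0
  pos <- denom > 0L
  pct[pos, ] <- 100 * counts[pos, , drop = FALSE] / denom[pos]
  new("HomologyMatrix", pct = pct, counts = counts, denominators = denom,
      species = species)
}

#' Transpose an Oxford grid
#'
#' Swaps the roles of linkage groups and model chromosomes: rows become the
#' model chromosomes and each cell is the percentage of a chromosome's
#' homologs found on each linkage group. A gene hit from two linkage
#' groups contributes to both, so transposed denominators count it twice.
#'
#' @param x a [HomologyMatrix-class].
#' @return a [HomologyMatrix-class] with transposed roles.
#' @export
transposeHomologyMatrix <- function(x) {
  stopifnot(is(x, "HomologyMatrix"))
  counts <- t(x@counts)
  denom <- as.integer(rowSums(counts))
  names(denom) <- rownames(counts)
  pct <- counts * 0
  pos <- denom > 0L
  pct[pos, ] <- 100 * counts[pos, , drop = FALSE] / denom[pos]
  new("HomologyMatrix", pct = pct, counts = counts, denominators = denom,
      species = x@species)
}

#' Classify homologous-chromosome relationships
#'
#' For each linkage group, model chromosomes holding strictly more than
#' `segmentThresholdPct` of its placed homologs are homologous segments.
#' The relationship class is `one-to-one` when exactly one chromosome
#' qualifies, `one-to-many` otherwise (`n_segments` gives k), and
#' `dispersed` when none does. Qualifying cells strictly above
#' `highlightThresholdPct` are tier `major`; cells between the thresholds
#' are tier `minor`.
#'
#' @param matrix a [HomologyMatrix-class].
#' @param config a [ChromoMapConfig-class].
#' @return data.frame with one row per qualifying (LG, chromosome):
#'   `linkage_group`, `chromosome`, `pct`, `tier`, `class`, `n_segments`
#'   (LGs with no qualifying chromosome contribute a single `dispersed`
#'   row with `NA` chromosome).
#' @export
classifyRelationships <- function(matrix, config = chromoMapConfig()) {
  stopifnot(is(matrix, "HomologyMatrix"), is(config, "ChromoMapConfig"))
  pct <- matrix@pct
  rows <- lapply(rownames(pct), function(lg) {
    v <- pct[lg, ]
    qual <- which(v > config@segmentThresholdPct)
    if (!length(qual)) {
      return(data.frame(linkage_group = lg, chromosome = NA_character_,
                        pct = NA_real_, tier = NA_character_,
                        class = "dispersed", n_segments = 0L,
                        stringsAsFactors = FALSE))
    }
    qual <- qual[order(-v[qual], names(v)[qual])]
    k <- length(qual)
    data.frame(
      linkage_group = lg,
      chromosome = names(v)[qual],
      pct = unname(v[qual]),
      tier = ifelse(v[qual] > config@highlightThresholdPct, "major", "minor"),
      class = if (k == 1L) "one-to-one" else "one-to-many",
      n_segments = k,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call fusion-like and fission-like chromosome patterns
#'
#' Uses both directions of the Oxford grid computed from the same
#' assignments. A linkage group homologous to k > 1 model chromosomes, each
#' of which maps back predominantly (strictly more than the highlight
#' threshold) to that linkage group, is called `fusion-like` (the target
#' chromosome looks like a fusion of the model chromosomes). The symmetric
#' pattern -- a model chromosome homologous to k > 1 linkage groups, each
#' mapping back predominantly to it -- is `fission-like`. Any other
#' multi-chromosome relationship is `complex`. An identity comparison
#' yields no calls.
#'
#' @param forward [HomologyMatrix-class], linkage groups in rows.
#' @param reverse [HomologyMatrix-class] with roles transposed; computed
#'   with [transposeHomologyMatrix()] when omitted.
#' @param config a [ChromoMapConfig-class].
#' @return data.frame `type` (`fusion-like`/`fission-like`/`complex`),
#'   `focal` (the LG for fusions, the model chromosome for fissions), `k`,
#'   `partners` (semicolon-joined, natural-sorted).
#' @export
detectFusionFission <- function(forward, reverse = transposeHomologyMatrix(forward),
                                config = chromoMapConfig()) {
  stopifnot(is(forward, "HomologyMatrix"), is(reverse, "HomologyMatrix"))
  seg <- config@segmentThresholdPct
  hi <- config@highlightThresholdPct
  fwd <- forward@pct
  rev <- reverse@pct
  calls <- list()
  add <- function(type, focal, partners) {
    calls[[length(calls) + 1L]] <<- data.frame(
      type = type, focal = focal, k = length(partners),
      partners = paste(.naturalSort(partners), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (lg in rownames(fwd)) {
    chrs <- colnames(fwd)[fwd[lg, ] > seg]
    if (length(chrs) < 2L) next
    back <- vapply(chrs, function(ch) {
      ch %in% rownames(rev) && lg %in% colnames(rev) && rev[ch, lg] > hi
    }, logical(1))
    add(if (all(back)) "fusion-like" else "complex", lg, chrs)
  }
  for (ch in rownames(rev)) {
    lgs <- colnames(rev)[rev[ch, ] > seg]
    if (length(lgs) < 2L) next
    back <- vapply(lgs, function(lg) {
      lg %in% rownames(fwd) && ch %in% colnames(fwd) && fwd[lg, ch] > hi
    }, logical(1))
    add(if (all(back)) "fission-like" else "complex", ch, lgs)
  }
  if (!length(calls)) {
    return(data.frame(type = character(), focal = character(), k = integer(),
                      partners = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
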