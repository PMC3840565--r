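# Shared fixture builders and independent oracles.

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

markerFile <- function(rows) {
  writeTempTsv(c("marker_id\tlinkage_group\tposition_cm\tsource_bac_id", rows))
}

# Small in-memory annotation: one species, genes laid out on chromosomes
# with 1000 bp genes and 1000 bp gaps.
makeAnnotation <- function(genesPerChrom, species = "model") {
  rows <- lapply(names(genesPerChrom), function(ch) {
    n <- genesPerChrom[[ch]]
    starts <- (seq_len(n) - 1L) * 2000L + 1L
    data.frame(species = species,
               gene_id = sprintf("%s_g%04d", ch, seq_len(n)),
               chromosome = ch, start_bp = starts,
               end_bp = starts + 999L, stringsAsFactors = FALSE)
  })
  assignGeneRanks(do.call(rbind, rows))
}

makeHit <- function(query, qs, qe, subject, evalue = 1e-50, bitscore = 100) {
  data.frame(query_id = query, query_start = as.integer(qs),
             query_end = as.integer(qe), subject_id = subject,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

# Minimal anchored-scaffold data.frame for joining tests.
makeAnchored <- function(scaffold_id, linkage_group, position_cm = 0) {
  data.frame(scaffold_id = scaffold_id, linkage_group = linkage_group,
             position_cm = position_cm, n_chains = 1L, status = "ANCHORED",
             stringsAsFactors = FALSE)
}

# Independent brute-force N50: try every observed length as the candidate L
# and keep the largest that is covered by at least half the total.
bruteN50 <- function(lengths) {
  if (!length(lengths)) return(0)
  cand <- sort(unique(lengths), decreasing = TRUE)
  tot <- sum(lengths)
  for (L in cand) if (sum(lengths[lengths >= L]) >= tot / 2) return(L)
  min(lengths)
}

# Independent brute-force enumeration of maximal near-consecutive-rank runs:
# for every pair of occupied ranks test the defining property directly.
bruteMaximalRuns <- function(ranks, maxGap = 0L) {
  ranks <- sort(unique(ranks))
  if (!length(ranks)) return(list())
  runs <- list()
  current <- ranks[[1L]]
  for (r in ranks[-1L]) {
    if (r - current[[length(current)]] <= 1L + maxGap) {
      current <- c(current, r)
    } else {
      runs[[length(runs) + 1L]] <- current
      current <- r
    }
  }
  runs[[length(runs) + 1L]] <- current
  runs
}

# Build LG-annotated assignments directly from (scaffold, gene) pairs.
assignmentsFor <- function(annotation, scaffold_id, gene_id,
                           linkage_group = "LG1") {
  i <- match(gene_id, annotation$gene_id)
  data.frame(scaffold_id = scaffold_id,
             query_start = seq_along(gene_id) * 100L,
             query_end = seq_along(gene_id) * 100L + 50L,
             gene_id = gene_id,
             species = annotation$species[i],
             chromosome = annotation$chromosome[i],
             gene_start_bp = annotation$start_bp[i],
             gene_end_bp = annotation$end_bp[i],
             rank = annotation$rank[i],
             evalue = 1e-50, bitscore = 100,
             linkage_group = linkage_group, position_cm = 0,
             placed = annotation$chromosome[i] != "UNPLACED",
             stringsAsFactors = FALSE)
}

# A homology matrix built straight from per-LG chromosome counts.
matrixFromCounts <- function(countsByLG) {
  rows <- lapply(names(countsByLG), function(lg) {
    v <- countsByLG[[lg]]
    data.frame(linkage_group = lg,
               gene_id = sprintf("%s_%s_g%03d", lg, rep(names(v), v),
                                 seq_len(sum(v))),
               chromosome = rep(names(v), v),
               placed = TRUE, stringsAsFactors = FALSE)
  })
  buildHomologyMatrix(do.call(rbind, rows))
}
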