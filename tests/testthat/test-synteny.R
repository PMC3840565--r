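# Conserved-block detection, summaries and truth comparison.

test_that("blocks are maximal near-consecutive-rank runs of >= 2 genes", {
  ann <- makeAnnotation(list(chr1 = 10))
  g <- ann$gene_id
  # ranks {2,3,5}: one block {2,3} under strict adjacency
  lga <- assignmentsFor(ann, "S1", g[c(2, 3, 5)])
  b <- detectSyntenyBlocks(lga, ann)
  expect_equal(nrow(b), 1L)
  expect_equal(b$gene_ids, paste(g[2:3], collapse = ";"))
  expect_equal(b$n_genes, 2L)
  # span in model coordinates: first gene start to last gene end
  expect_equal(b$model_start_bp, ann$start_bp[[2L]])
  expect_equal(b$model_end_bp, ann$end_bp[[3L]])
  expect_equal(b$span_bp, ann$end_bp[[3L]] - ann$start_bp[[2L]] + 1L)

  # a single gene never forms a block
  expect_equal(nrow(detectSyntenyBlocks(assignmentsFor(ann, "S1", g[[4L]]),
                                        ann)), 0L)

  # a rank gap of one is bridged by maxRankGap = 1
  b2 <- detectSyntenyBlocks(lga, ann, syntenyConfig(maxRankGap = 1))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$n_genes, 3L)

  # blocks never span scaffolds
  lga3 <- rbind(assignmentsFor(ann, "S1", g[1:2]),
                assignmentsFor(ann, "S2", g[3:4]))
  b3 <- detectSyntenyBlocks(lga3, ann)
  expect_equal(b3$scaffold_id, c("S1", "S2"))
})

test_that("assignments to unplaced genes are skipped with a count", {
  ann <- rbind(makeAnnotation(list(chr1 = 4)),
               assignGeneRanks(data.frame(species = "model", gene_id = "gU",
                                          chromosome = "UNPLACED",
                                          start_bp = 1L, end_bp = 10L)))
  lga <- assignmentsFor(ann, "S1", c(ann$gene_id[1:2], "gU"))
  expect_message(b <- detectSyntenyBlocks(lga, ann), "1 assignment")
  expect_equal(nrow(b), 1L)
})

test_that("HIT_ONLY adjacency bridges unhit annotation genes", {
  ann <- makeAnnotation(list(chr1 = 10))
  g <- ann$gene_id
  # hits to ranks 2, 4, 6 only: no blocks under ALL_ANNOTATED,
  # one 3-gene block when ranks densify over hit genes
  lga <- assignmentsFor(ann, "S1", g[c(2, 4, 6)])
  expect_equal(nrow(detectSyntenyBlocks(lga, ann)), 0L)
  bh <- detectSyntenyBlocks(lga, ann,
                            syntenyConfig(adjacencyUniverse = "HIT_ONLY"))
  expect_equal(nrow(bh), 1L)
  expect_equal(bh$n_genes, 3L)
})

test_that("detection agrees with brute-force run enumeration", {
  ann <- makeAnnotation(list(chr1 = 500, chr2 = 500))
  set.seed(99)
  for (i in 1:25) {
    gap <- sample(0:2, 1L)
    cfgS <- syntenyConfig(maxRankGap = gap)
    lga <- do.call(rbind, lapply(1:4, function(s) {
      picks <- sample(ann$gene_id, sample(5:80, 1L))
      assignmentsFor(ann, sprintf("S%d", s), picks)
    }))
    blocks <- detectSyntenyBlocks(lga, ann, cfgS)
    # oracle: enumerate runs per (scaffold, chromosome) independently
    expected <- 0L
    for (s in unique(lga$scaffold_id)) {
      for (ch in unique(lga$chromosome)) {
        ranks <- lga$rank[lga$scaffold_id == s & lga$chromosome == ch]
        runs <- bruteMaximalRuns(ranks, gap)
        runs <- runs[lengths(runs) >= 2L]
        expected <- expected + length(runs)
        for (r in runs) {
          key <- paste(sort(ann$gene_id[ann$chromosome == ch &
                                          ann$rank %in% r]), collapse = ";")
          hit <- blocks$scaffold_id == s & blocks$model_chromosome == ch &
            vapply(strsplit(blocks$gene_ids, ";"), function(x)
              paste(sort(x), collapse = ";"), character(1)) == key
          expect_equal(sum(hit), 1L)
        }
      }
    }
    expect_equal(nrow(blocks), expected)
  }
})

test_that("genes in blocks never decrease as the rank gap grows", {
  ann <- makeAnnotation(list(chr1 = 200))
  set.seed(5)
  for (i in 1:10) {
    lga <- assignmentsFor(ann, "S1", sample(ann$gene_id, 60))
    tot <- vapply(0:3, function(g) {
      b <- detectSyntenyBlocks(lga, ann, syntenyConfig(maxRankGap = g))
      sum(b$n_genes)
    }, numeric(1))
    expect_true(all(diff(tot) >= 0))
  }
})

test_that("block partition is disjoint and conserved in summaries", {
  cfg <- simConfig(seed = 23, nChromosomes = 5, genesPerChromosome = 60,
                   nFusions = 1, nFissions = 1, nInversions = 2,
                   nTranslocations = 2)
  sim <- simulateComparativeGenomes(cfg)
  ev <- evidenceTables(sim)
  anc <- buildEvidenceChains(markerTable(sim), ev$bacContig,
                             ev$contigAnchors, ev$seqScaffold)
  lga <- homologsPerLinkageGroup(
    assignBestHits(filterHits(hitTable(sim)[, 1:6]), modelAnnotation(sim)),
    anc)
  blocks <- detectSyntenyBlocks(lga, modelAnnotation(sim))
  genes <- unlist(strsplit(blocks$gene_ids, ";"))
  expect_equal(anyDuplicated(genes), 0L)  # disjoint across blocks
  s <- summarizeBlocks(blocks)
  tot <- s[s$linkage_group == "Total", ]
  per <- s[s$linkage_group != "Total", ]
  expect_equal(tot$n_blocks, sum(per$n_blocks))
  expect_equal(tot$total_span_bp, sum(per$total_span_bp))
  expect_equal(tot$n_genes, sum(per$n_genes))
  expect_equal(tot$n_genes, sum(blocks$n_genes))
  expect_equal(tot$mean_span_bp, tot$total_span_bp / tot$n_blocks)
  expect_equal(tot$mean_genes_per_block, tot$n_genes / tot$n_blocks)
})

test_that("summary statistics match brute force on a known set", {
  blocks <- data.frame(
    block_id = c("a", "b", "c"), scaffold_id = "S1", linkage_group = "LG1",
    model_chromosome = "chr1", gene_ids = c("g1;g2", "g3;g4", "g5;g6"),
    n_genes = 2L, model_start_bp = 1L, model_end_bp = 1L,
    span_bp = c(100L, 200L, 300L), stringsAsFactors = FALSE)
  s <- summarizeBlocks(blocks)
  lg <- s[s$linkage_group == "LG1", ]
  expect_equal(lg$total_span_bp, 600)
  expect_equal(lg$mean_span_bp, 200)
  expect_equal(lg$max_span_bp, 300)
  expect_equal(lg$n50_span_bp, 300)   # 300 alone covers half of 600

  # single block: every statistic equals that block's values
  s1 <- summarizeBlocks(blocks[1L, ])
  lg1 <- s1[s1$linkage_group == "LG1", ]
  expect_equal(lg1$total_span_bp, 100)
  expect_equal(lg1$mean_span_bp, 100)
  expect_equal(lg1$n50_span_bp, 100)

  # empty set: defined all-zero summary
  s0 <- summarizeBlocks(blocks[0L, ])
  expect_equal(s0$n_blocks, 0L)
  expect_equal(s0$total_span_bp, 0)
})

test_that("truth comparison applies the edge-case conventions", {
  truth <- data.frame(scaffold_id = "S1", model_chromosome = "chr1",
                      gene_ids = "g1;g2", n_genes = 2L,
                      stringsAsFactors = FALSE)
  # empty detection vs non-empty truth: vacuous precision, zero recall
  r <- compareToTruth(data.frame(), truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0)
  # perfect match
  det <- data.frame(scaffold_id = "S1", model_chromosome = "chr1",
                    gene_ids = "g2;g1", stringsAsFactors = FALSE)
  r2 <- compareToTruth(det, truth)
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 1)
  expect_equal(r2$exact_match_fraction, 1)
})

test_that("gene loss under HIT_ONLY adjacency cannot lower recall", {
  # Truth here is contiguity among SURVIVING genes: maximal runs of genes
  # consecutive among the survivors of a model chromosome within one
  # scaffold. Gene loss punches holes in the full-annotation rank space,
  # so ALL_ANNOTATED detection splits these runs while HIT_ONLY does not.
  cfg <- simConfig(seed = 37, nChromosomes = 4, genesPerChromosome = 80,
                   nFusions = 0, nFissions = 0, nInversions = 2,
                   nTranslocations = 1, geneLossRate = 0.1)
  sim <- simulateComparativeGenomes(cfg)
  ann <- modelAnnotation(sim)
  tg <- targetGenes(sim)
  surv <- assignGeneRanks(ann[ann$gene_id %in% tg$gene_id, ])
  rankOf <- setNames(surv$rank, surv$gene_id)
  truth <- do.call(rbind, lapply(
    split(tg, paste(tg$scaffold_id, tg$model_chromosome, sep = "\r")),
    function(g) {
      g <- g[order(rankOf[g$gene_id]), ]
      runid <- cumsum(c(1L, diff(rankOf[g$gene_id]) > 1L))
      do.call(rbind, lapply(split(g$gene_id, runid), function(ids) {
        data.frame(scaffold_id = g$scaffold_id[[1L]],
                   model_chromosome = g$model_chromosome[[1L]],
                   gene_ids = paste(ids, collapse = ";"),
                   n_genes = length(ids), stringsAsFactors = FALSE)
      }))
    }))
  ev <- evidenceTables(sim)
  anc <- buildEvidenceChains(markerTable(sim), ev$bacContig,
                             ev$contigAnchors, ev$seqScaffold)
  lga <- homologsPerLinkageGroup(
    assignBestHits(filterHits(hitTable(sim)[, 1:6]), ann), anc)
  recallOf <- function(universe) {
    blocks <- detectSyntenyBlocks(lga, ann,
                                  syntenyConfig(adjacencyUniverse = universe))
    compareToTruth(blocks, truth)$recall
  }
  rHit <- recallOf("HIT_ONLY")
  rAll <- recallOf("ALL_ANNOTATED")
  expect_gte(rHit, rAll)
  expect_equal(rHit, 1)  # all survivors are hit, so recovery is exact
})
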