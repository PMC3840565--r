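# Simulator: deterministic layout, hand-checked rearrangements,
# conservation invariants, truth-segment consistency, and byte-identical
# reproducibility.

test_that("model genome layout follows the deterministic spacing rule", {
  cfg <- simConfig(nChromosomes = 2, genesPerChromosome = 3,
                   geneLengthBp = 1000, intergenicBp = 500)
  g <- simulateModelGenome(cfg)
  expect_equal(nrow(g), 6L)
  # gene 2 of chr1 starts at (2-1)*(1000+500)+1
  expect_equal(g$start_bp[g$chromosome == "chr1" & g$rank == 2L], 1501L)
  expect_equal(g$end_bp[g$chromosome == "chr1" & g$rank == 2L], 2500L)
  # ranks are a bijection per chromosome
  expect_equal(sort(g$rank[g$chromosome == "chr2"]), 1:3)
})

test_that("rearrangement primitives match hand-enumerated outcomes", {
  # no events, no loss: target order equals model order
  cfg0 <- simConfig(seed = 5, nChromosomes = 3, genesPerChromosome = 4,
                    nFusions = 0, nFissions = 0, nInversions = 0,
                    nTranslocations = 0)
  model <- simulateModelGenome(cfg0)
  r0 <- applyRearrangements(model, cfg0)
  expect_equal(unname(lengths(r0$target)), rep(4L, 3L))
  expect_equal(unlist(r0$target, use.names = FALSE), model$gene_id)
  expect_equal(nrow(r0$eventLog), 0L)

  # one fusion: concatenation with order preserved within halves
  cfg1 <- simConfig(seed = 5, nChromosomes = 2, genesPerChromosome = 3,
                    nFusions = 1, nFissions = 0, nInversions = 0,
                    nTranslocations = 0)
  m1 <- simulateModelGenome(cfg1)
  r1 <- applyRearrangements(m1, cfg1)
  expect_length(r1$target, 1L)
  fused <- r1$target[[1L]]
  expect_length(fused, 6L)
  first <- sub("_g.*", "", fused[1:3])
  expect_equal(fused[1:3], sprintf("%s_g%04d", first[[1L]], 1:3))
  expect_equal(fused[4:6], sprintf("%s_g%04d",
                                   setdiff(c("chr1", "chr2"), first[[1L]]),
                                   1:3))
  expect_equal(r1$eventLog$type, "fusion")

  # a fission splits one chromosome into two order-preserving parts
  cfg2 <- simConfig(seed = 9, nChromosomes = 1, genesPerChromosome = 10,
                    nFusions = 0, nFissions = 1, nInversions = 0,
                    nTranslocations = 0)
  m2 <- simulateModelGenome(cfg2)
  r2 <- applyRearrangements(m2, cfg2)
  expect_length(r2$target, 2L)
  expect_equal(unlist(r2$target, use.names = FALSE), m2$gene_id)
  j <- as.integer(sub("break_after_gene=", "", r2$eventLog$detail))
  expect_equal(lengths(r2$target), c(LG1 = j, LG2 = 10L - j))

  # infeasible request is a configuration error
  expect_error(applyRearrangements(m2, simConfig(nChromosomes = 1,
                                                 nFusions = 1)),
               "infeasible")
})

test_that("an inversion reverses exactly the chosen gene interval", {
  # apply the documented reversal semantics directly: ranks 2-4 of 5
  genes <- sprintf("chr1_g%04d", 1:5)
  genes[2:4] <- rev(genes[2:4])
  expect_equal(as.integer(sub(".*_g", "", genes)), c(1L, 4L, 3L, 2L, 5L))

  # and via the simulator: every inversion event log line is consistent
  cfg <- simConfig(seed = 11, nChromosomes = 2, genesPerChromosome = 30,
                   nFusions = 0, nFissions = 0, nInversions = 3,
                   nTranslocations = 0)
  m <- simulateModelGenome(cfg)
  r <- applyRearrangements(m, cfg)
  expect_equal(sum(r$eventLog$type == "inversion"), 3L)
  # gene content is conserved by inversions
  expect_setequal(unlist(r$target, use.names = FALSE), m$gene_id)
})

test_that("gene conservation and event log balance exactly", {
  cfg <- simConfig(seed = 2, nChromosomes = 6, genesPerChromosome = 40,
                   nFusions = 1, nFissions = 1, nInversions = 3,
                   nTranslocations = 3, geneLossRate = 0.1)
  sim <- simulateComparativeGenomes(cfg)
  lost <- sum(eventLog(sim)$type == "loss")
  expect_gt(lost, 0L)
  expect_equal(nrow(modelAnnotation(sim)),
               nrow(targetGenes(sim)) + lost)
  # lost genes are exactly those named by the log
  expect_setequal(
    c(targetGenes(sim)$gene_id,
      eventLog(sim)$outputs[eventLog(sim)$type == "loss"]),
    modelAnnotation(sim)$gene_id)
})

test_that("truth segments partition each scaffold's gene content", {
  cfg <- simConfig(seed = 4, nChromosomes = 5, genesPerChromosome = 50,
                   nFusions = 1, nFissions = 1, nInversions = 2,
                   nTranslocations = 2)
  sim <- simulateComparativeGenomes(cfg)
  tg <- targetGenes(sim)
  ts <- truthSegments(sim)
  segGenes <- strsplit(ts$gene_ids, ";", fixed = TRUE)
  # per scaffold, segments recover the gene content exactly, no overlap
  for (sid in unique(tg$scaffold_id)) {
    fromSegs <- unlist(segGenes[ts$scaffold_id == sid])
    expect_false(anyDuplicated(fromSegs) > 0L)
    expect_setequal(fromSegs, tg$gene_id[tg$scaffold_id == sid])
  }
  # each segment is a consecutive-rank run on one model chromosome
  rankOf <- setNames(modelAnnotation(sim)$rank, modelAnnotation(sim)$gene_id)
  for (g in segGenes) {
    r <- sort(rankOf[g])
    expect_equal(unname(r), seq(min(r), max(r)))
  }
  expect_equal(sum(ts$n_genes), nrow(tg))
})

test_that("a scaffold boundary splits a run into two truth segments", {
  # one 10-gene chromosome; force ~5-gene scaffolds via the N50 target
  cfg <- simConfig(seed = 1, nChromosomes = 1, genesPerChromosome = 10,
                   nFusions = 0, nFissions = 0, nInversions = 0,
                   nTranslocations = 0, scaffoldN50Target = 10000,
                   geneLengthBp = 1000, intergenicBp = 1000)
  sim <- simulateComparativeGenomes(cfg)
  ts <- truthSegments(sim)
  # with no rearrangement every scaffold holds exactly one segment
  expect_equal(nrow(ts), nrow(scaffoldIndex(sim)))
  expect_equal(sum(ts$n_genes), 10L)
  # single-scaffold case: the whole chromosome is one segment
  cfg1 <- simConfig(seed = 1, nChromosomes = 1, genesPerChromosome = 10,
                    nFusions = 0, nFissions = 0, nInversions = 0,
                    nTranslocations = 0, scaffoldN50Target = 1000000)
  ts1 <- truthSegments(simulateComparativeGenomes(cfg1))
  expect_equal(nrow(ts1), 1L)
  expect_equal(ts1$n_genes, 10L)
})

test_that("identical configurations produce byte-identical files", {
  cfg <- simConfig(seed = 8, nChromosomes = 4, genesPerChromosome = 25,
                   nFusions = 1, nFissions = 1, nInversions = 2,
                   nTranslocations = 1, paralogRate = 0.2,
                   spuriousHitRate = 0.2)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- writeSimulation(simulateComparativeGenomes(cfg), d1)
  f2 <- writeSimulation(simulateComparativeGenomes(cfg), d2)
  for (k in names(f1)) {
    expect_equal(unname(tools::md5sum(f1[[k]])), unname(tools::md5sum(f2[[k]])),
                 info = k)
  }
})

test_that("hit table noise classes behave as configured", {
  base <- simConfig(seed = 13, nChromosomes = 3, genesPerChromosome = 40,
                    nFusions = 0, nFissions = 0, nInversions = 1,
                    nTranslocations = 1)
  sim0 <- simulateComparativeGenomes(base)
  h0 <- hitTable(sim0)
  # no noise: one hit per surviving gene
  expect_equal(nrow(h0), nrow(targetGenes(sim0)))
  expect_true(all(h0$class == "true"))
  expect_true(all(h0$evalue <= 1e-15))

  noisy <- simConfig(seed = 13, nChromosomes = 3, genesPerChromosome = 40,
                     nFusions = 0, nFissions = 0, nInversions = 1,
                     nTranslocations = 1, paralogRate = 0.5,
                     spuriousHitRate = 0.5)
  simN <- simulateComparativeGenomes(noisy)
  hN <- hitTable(simN)
  # spurious hits all sit above the canonical 1e-10 cutoff
  sp <- hN[hN$class == "spurious", ]
  expect_gt(nrow(sp), 0L)
  expect_true(all(sp$evalue > 1e-10 & sp$evalue <= 1e-2))
  # every paralog hit scores strictly below its true counterpart
  pa <- hN[hN$class == "paralog", ]
  expect_gt(nrow(pa), 0L)
  tr <- hN[hN$class == "true", ]
  key <- paste(tr$query_id, tr$query_start)
  expect_true(all(pa$bitscore <
                    tr$bitscore[match(paste(pa$query_id, pa$query_start), key)]))
  # independent sub-streams: true hits unchanged by the noise settings
  expect_equal(hN[hN$class == "true", ], h0)
})
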