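# Evidence-chain anchoring and assembly statistics.

mk1 <- data.frame(marker_id = "m1", linkage_group = "LG1", position_cm = 3.5,
                  source_bac_id = "bacA", stringsAsFactors = FALSE)

test_that("a single complete chain anchors a scaffold at its marker", {
  res <- buildEvidenceChains(
    mk1,
    data.frame(bac_id = "bacA", contig_id = "C1"),
    data.frame(contig_id = "C1", anchor_seq_id = "s1",
               anchor_seq_kind = "PMCSS"),
    data.frame(anchor_seq_id = "s1", scaffold_id = "S1"))
  a <- anchoredScaffolds(res)
  expect_equal(a$scaffold_id, "S1")
  expect_equal(a$linkage_group, "LG1")
  expect_equal(a$position_cm, 3.5)
  expect_equal(a$n_chains, 1L)
  ev <- evidenceChains(res)
  expect_equal(ev$marker_id, "m1")
  expect_equal(ev$bac_id, "bacA")
  expect_equal(ev$contig_id, "C1")
})

test_that("multi-linkage-group support is a conflict under the drop policy", {
  mk <- data.frame(marker_id = c("m1", "m7"),
                   linkage_group = c("LG1", "LG7"),
                   position_cm = c(0, 10),
                   source_bac_id = c("bacA", "bacB"),
                   stringsAsFactors = FALSE)
  b2c <- data.frame(bac_id = c("bacA", "bacB"), contig_id = c("C1", "C7"))
  cas <- data.frame(contig_id = c("C1", "C7"),
                    anchor_seq_id = c("s1", "s7"),
                    anchor_seq_kind = c("BES", "PMCSS"))
  s2s <- data.frame(anchor_seq_id = c("s1", "s7"),
                    scaffold_id = c("S1", "S1"))
  expect_message(res <- buildEvidenceChains(mk, b2c, cas, s2s), "CONFLICT")
  expect_equal(nrow(anchoredScaffolds(res)), 0L)
  expect_equal(conflictedScaffolds(res)$status, "CONFLICT")

  # best-support policy resolves when one LG has more chains
  s2s2 <- rbind(s2s, data.frame(anchor_seq_id = "s1b", scaffold_id = "S1"))
  cas2 <- rbind(cas, data.frame(contig_id = "C1", anchor_seq_id = "s1b",
                                anchor_seq_kind = "BES"))
  res2 <- buildEvidenceChains(mk, b2c, cas2, s2s2,
                              conflictPolicy = "best-support")
  expect_equal(anchoredScaffolds(res2)$linkage_group, "LG1")
  # an exact tie still drops
  expect_message(
    res3 <- buildEvidenceChains(mk, b2c, cas, s2s,
                                conflictPolicy = "best-support"),
    "CONFLICT")
  expect_equal(nrow(anchoredScaffolds(res3)), 0L)
})

test_that("multi-marker support takes the median cM position", {
  mk <- data.frame(marker_id = c("m1", "m2", "m3"),
                   linkage_group = "LG2",
                   position_cm = c(1, 4, 100),  # median robust to outlier
                   source_bac_id = c("bA", "bB", "bC"),
                   stringsAsFactors = FALSE)
  b2c <- data.frame(bac_id = c("bA", "bB", "bC"),
                    contig_id = c("C1", "C2", "C3"))
  cas <- data.frame(contig_id = c("C1", "C2", "C3"),
                    anchor_seq_id = c("s1", "s2", "s3"),
                    anchor_seq_kind = "PMCSS")
  s2s <- data.frame(anchor_seq_id = c("s1", "s2", "s3"), scaffold_id = "S9")
  res <- buildEvidenceChains(mk, b2c, cas, s2s)
  expect_equal(anchoredScaffolds(res)$position_cm, 4)
  expect_equal(anchoredScaffolds(res)$n_chains, 3L)
})

test_that("dangling scaffold references are integrity errors in strict mode", {
  s2s <- data.frame(anchor_seq_id = "s1", scaffold_id = "GHOST")
  scafs <- data.frame(scaffold_id = "S1", length_bp = 100L)
  expect_error(
    buildEvidenceChains(mk1, data.frame(bac_id = "bacA", contig_id = "C1"),
                        data.frame(contig_id = "C1", anchor_seq_id = "s1",
                                   anchor_seq_kind = "BES"),
                        s2s, scaffolds = scafs),
    "GHOST")
  expect_warning(
    res <- buildEvidenceChains(mk1,
                               data.frame(bac_id = "bacA", contig_id = "C1"),
                               data.frame(contig_id = "C1",
                                          anchor_seq_id = "s1",
                                          anchor_seq_kind = "BES"),
                               s2s, scaffolds = scafs, strict = FALSE),
    "unknown scaffold")
  expect_equal(nrow(anchoredScaffolds(res)), 0L)
})

test_that("every anchored chain re-verifies link by link against the inputs", {
  cfg <- simConfig(seed = 21, nChromosomes = 4, genesPerChromosome = 40,
                   nFusions = 1, nFissions = 1, nInversions = 1,
                   nTranslocations = 1)
  sim <- simulateComparativeGenomes(cfg)
  ev <- evidenceTables(sim)
  res <- buildEvidenceChains(markerTable(sim), ev$bacContig,
                             ev$contigAnchors, ev$seqScaffold,
                             scaffolds = scaffoldIndex(sim)[, 1:2])
  ch <- evidenceChains(res)
  mk <- markerTable(sim)
  # marker -> BAC
  expect_equal(ch$bac_id, mk$source_bac_id[match(ch$marker_id, mk$marker_id)])
  # BAC -> contig
  b2c <- ev$bacContig
  expect_true(all(paste(ch$bac_id, ch$contig_id) %in%
                    paste(b2c$bac_id, b2c$contig_id)))
  # contig -> anchor sequence (with kind)
  cas <- ev$contigAnchors
  expect_true(all(paste(ch$contig_id, ch$anchor_seq_id, ch$anchor_seq_kind) %in%
                    paste(cas$contig_id, cas$anchor_seq_id,
                          cas$anchor_seq_kind)))
  # anchor sequence -> scaffold
  s2s <- ev$seqScaffold
  expect_true(all(paste(ch$anchor_seq_id, ch$scaffold_id) %in%
                    paste(s2s$anchor_seq_id, s2s$scaffold_id)))
  # on a no-noise full-evidence simulation every scaffold anchors to its
  # true linkage group
  a <- anchoredScaffolds(res)
  truthLG <- scaffoldIndex(sim)$linkage_group
  expect_equal(nrow(a), nrow(scaffoldIndex(sim)))
  expect_equal(a$linkage_group[match(scaffoldIndex(sim)$scaffold_id,
                                     a$scaffold_id)], truthLG)
})

test_that("N50 follows the standard cumulative-half rule", {
  expect_equal(computeN50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(computeN50(7), 7)       # single element
  expect_equal(computeN50(numeric()), 0)
  # brute-force agreement on random fixtures
  set.seed(42)
  for (i in 1:50) {
    lens <- sample.int(10000L, sample.int(200L, 1L), replace = TRUE)
    expect_equal(computeN50(lens), bruteN50(lens))
  }
})

test_that("anchoring statistics match hand-computed values", {
  scafs <- data.frame(scaffold_id = sprintf("S%d", 1:5),
                      length_bp = c(5L, 4L, 3L, 2L, 1L))
  st <- computeAnchorStats(scafs, scafs$scaffold_id)
  expect_equal(st@n50Bp, 4)
  expect_equal(st@anchoredFraction, 1.0)
  expect_equal(anchoredPercent(st), 100)

  # partial anchoring
  st2 <- computeAnchorStats(scafs, c("S1", "S3"))
  expect_equal(st2@nAnchored, 2L)
  expect_equal(st2@anchoredLengthBp, 8)
  expect_equal(st2@anchoredFraction, 8 / 15)

  # empty assembly yields a defined all-zero summary
  st0 <- computeAnchorStats(data.frame(scaffold_id = character(),
                                       length_bp = integer()),
                            character())
  expect_equal(st0@nScaffolds, 0L)
  expect_equal(st0@n50Bp, 0)
  expect_equal(st0@anchoredFraction, 0)

  # unknown anchored id is an error
  expect_error(computeAnchorStats(scafs, "NOPE"), "unknown scaffold")
})

test_that("adding consistent evidence never shrinks the anchored set", {
  mk <- data.frame(marker_id = c("m1", "m2"), linkage_group = "LG1",
                   position_cm = c(0, 5), source_bac_id = c("bA", "bB"),
                   stringsAsFactors = FALSE)
  b2c <- data.frame(bac_id = c("bA", "bB"), contig_id = c("C1", "C2"))
  cas1 <- data.frame(contig_id = "C1", anchor_seq_id = "s1",
                     anchor_seq_kind = "BES")
  s2s1 <- data.frame(anchor_seq_id = "s1", scaffold_id = "S1")
  n1 <- nrow(anchoredScaffolds(buildEvidenceChains(mk, b2c, cas1, s2s1)))
  cas2 <- rbind(cas1, data.frame(contig_id = "C2", anchor_seq_id = "s2",
                                 anchor_seq_kind = "PMCSS"))
  s2s2 <- rbind(s2s1, data.frame(anchor_seq_id = "s2", scaffold_id = "S2"))
  n2 <- nrow(anchoredScaffolds(buildEvidenceChains(mk, b2c, cas2, s2s2)))
  expect_gte(n2, n1)
})
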