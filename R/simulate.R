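# Seeded comparative-genome simulator. A model genome with a deterministic
# gene layout is rearranged into a target genome (fusions, fissions,
# inversions, translocations, gene loss), fragmented into scaffolds with a
# full marker/BAC/physical-contig/anchor-sequence evidence chain, and paired
# with a noisy protein-alignment hit table. Every downstream stage has a
# ground-truth file to validate against.
#
# Rearrangements operate on gene-order space; physical coordinates are
# re-laid-out after the events, matching the gene-order character of the
# downstream analysis.

.resample <- function(x, k = 1L) x[sample.int(length(x), k)]

#' Simulate a model-species gene annotation
#'
#' Lays out `nChromosomes` chromosomes each carrying `genesPerChromosome`
#' genes at deterministic coordinates: gene i starts at
#' `(i-1)*(geneLengthBp+intergenicBp)+1`. Gene ids encode chromosome and
#' rank, so ground truth is readable from the id.
#'
#' @param config a [SimConfig-class].
#' @return gene annotation data.frame (`species`, `gene_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `rank`).
#' @examples
#' head(simulateModelGenome(simConfig(nChromosomes = 2, genesPerChromosome = 3)))
#' @export
simulateModelGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  unit <- config@geneLengthBp + config@intergenicBp
  chroms <- sprintf("chr%d", seq_len(config@nChromosomes))
  n <- config@genesPerChromosome
  idx <- seq_len(n)
  starts <- (idx - 1L) * unit + 1L
  out <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(species = "model",
               gene_id = sprintf("%s_g%04d", ch, idx),
               chromosome = ch,
               start_bp = starts,
               end_bp = starts + config@geneLengthBp - 1L,
               rank = idx,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apply a rearrangement history to a model genome
#'
#' Derives a target gene order from the model annotation by applying, in
#' fixed stage order, fusions (concatenation of two chromosomes), fissions
#' (split at a gene boundary drawn from the central 20--80% of the gene
#' order), inversions (reversal of a 2--50 gene interval), translocations
#' (movement of a 1--20 gene interval between chromosomes), and per-gene
#' loss. Fusion and fission targets are distinct model chromosomes, so each
#' chromosome undergoes at most one membership-changing event and the event
#' log stays directly interpretable. Genes keep their model ids. The
#' resulting chromosomes are relabelled `LG1..LGk` in derivation order.
#'
#' @param model model annotation from [simulateModelGenome()].
#' @param config a [SimConfig-class].
#' @return list with `target` (named list of gene-id vectors, one per
#'   linkage group, in target order), `eventLog` (data.frame: `step`,
#'   `type`, `inputs`, `outputs`, `detail`, `n_genes`), and `chromMap`
#'   (provisional name -> final LG label).
#' @export
applyRearrangements <- function(model, config) {
  stopifnot(is(config, "SimConfig"))
  chrs <- split(model$gene_id, model$chromosome)
  chrs <- chrs[.naturalSort(names(chrs))]
  if (2L * config@nFusions + config@nFissions > length(chrs))
    .stopf("infeasible event request: %d fusions + %d fissions need %d distinct chromosomes, have %d",
           config@nFusions, config@nFissions,
           2L * config@nFusions + config@nFissions, length(chrs))
  log <- list()
  step <- 0L
  addLog <- function(type, inputs, outputs, detail, n) {
    step <<- step + 1L
    log[[step]] <<- data.frame(step = step, type = type,
                               inputs = paste(inputs, collapse = ";"),
                               outputs = paste(outputs, collapse = ";"),
                               detail = detail, n_genes = n,
                               stringsAsFactors = FALSE)
  }

  set.seed(.stageSeed(config@seed, 1L))
  pool <- names(chrs)  # chromosomes not yet used by a fusion or fission

  for (i in seq_len(config@nFusions)) {
    pair <- .resample(pool, 2L)
    pool <- setdiff(pool, pair)
    newname <- sprintf("fusion%d", i)
    chrs[[newname]] <- c(chrs[[pair[[1L]]]], chrs[[pair[[2L]]]])
    chrs[pair] <- NULL
    addLog("fusion", pair, newname, "", length(chrs[[newname]]))
  }

  for (i in seq_len(config@nFissions)) {
    cand <- pool[vapply(pool, function(p) length(chrs[[p]]) >= 2L, logical(1))]
    if (!length(cand))
      .stopf("infeasible event request: no chromosome with >= 2 genes left for fission")
    ch <- .resample(cand, 1L)
    pool <- setdiff(pool, ch)
    n <- length(chrs[[ch]])
    lo <- max(1L, ceiling(0.2 * n)); hi <- min(n - 1L, floor(0.8 * n))
    if (lo > hi) { lo <- 1L; hi <- n - 1L }
    j <- .resample(seq(lo, hi), 1L)
    parts <- c(sprintf("%s_p1", ch), sprintf("%s_p2", ch))
    g <- chrs[[ch]]
    chrs[[parts[[1L]]]] <- g[seq_len(j)]
    chrs[[parts[[2L]]]] <- g[seq(j + 1L, n)]
    chrs[[ch]] <- NULL
    addLog("fission", ch, parts, sprintf("break_after_gene=%d", j), n)
  }

  for (i in seq_len(config@nInversions)) {
    cand <- names(chrs)[lengths(chrs) >= 2L]
    ch <- .resample(cand, 1L)
    n <- length(chrs[[ch]])
    len <- .resample(seq(2L, min(n, 50L)), 1L)
    s <- .resample(seq_len(n - len + 1L), 1L)
    rng <- seq(s, s + len - 1L)
    chrs[[ch]][rng] <- rev(chrs[[ch]][rng])
    addLog("inversion", ch, ch, sprintf("genes=%d-%d", s, s + len - 1L), len)
  }

  for (i in seq_len(config@nTranslocations)) {
    cand <- names(chrs)[lengths(chrs) >= 2L]
    if (length(cand) < 1L || length(chrs) < 2L) break
    don <- .resample(cand, 1L)
    n <- length(chrs[[don]])
    len <- .resample(seq_len(min(n - 1L, 20L)), 1L)
    s <- .resample(seq_len(n - len + 1L), 1L)
    seg <- chrs[[don]][seq(s, s + len - 1L)]
    chrs[[don]] <- chrs[[don]][-seq(s, s + len - 1L)]
    rec <- .resample(setdiff(names(chrs), don), 1L)
    m <- length(chrs[[rec]])
    at <- .resample(seq(0L, m), 1L)
    chrs[[rec]] <- append(chrs[[rec]], seg, after = at)
    addLog("translocation", c(don, rec), c(don, rec),
           sprintf("genes=%d-%d;insert_after=%d", s, s + len - 1L, at), len)
  }

  if (config@geneLossRate > 0) {
    set.seed(.stageSeed(config@seed, 2L))
    for (ch in names(chrs)) {
      drop <- stats::runif(length(chrs[[ch]])) < config@geneLossRate
      # keep at least one gene per chromosome
      if (all(drop)) drop[[1L]] <- FALSE
      for (g in chrs[[ch]][drop]) addLog("loss", ch, g, "", 1L)
      chrs[[ch]] <- chrs[[ch]][!drop]
    }
  }

  final <- sprintf("LG%d", seq_along(chrs))
  chromMap <- stats::setNames(final, names(chrs))
  names(chrs) <- final
  logdf <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), type = character(), inputs = character(),
               outputs = character(), detail = character(),
               n_genes = integer(), stringsAsFactors = FALSE)
  translate <- function(x) {
    vapply(strsplit(x, ";", fixed = TRUE), function(v) {
      paste(ifelse(v %in% names(chromMap), unname(chromMap[v]), v),
            collapse = ";")
    }, character(1))
  }
  logdf$inputs <- translate(logdf$inputs)
  logdf$outputs <- translate(logdf$outputs)
  list(target = chrs, eventLog = logdf, chromMap = chromMap)
}

#' Fragment a target genome into scaffolds with anchoring evidence
#'
#' Re-lays out each target chromosome with the model gene spacing, cuts it
#' into scaffolds whose gene counts are drawn to approximate the configured
#' scaffold N50, places microsatellite markers at the configured density
#' (cM = physical Mb x `cmPerMb`, binned at `mapResolutionCm`, which stacks
#' scaffolds at shared map positions), and builds the evidence tables: one
#' BAC and one physical-map contig per marker, and per-scaffold anchor
#' sequences (BES or PMCSS) attached to the contigs of the markers spanning
#' the scaffold (nearest marker if none falls inside). Ground-truth
#' segments record, per scaffold and model chromosome, the maximal runs of
#' genes with consecutive model ranks.
#'
#' @param target named list of gene-id vectors from [applyRearrangements()].
#' @param model model annotation (source of ranks and model coordinates).
#' @param config a [SimConfig-class].
#' @return list of data.frames: `targetGenes`, `scaffolds`, `markers`,
#'   `bacContig`, `contigAnchors`, `seqScaffold`, `truthSegments`.
#' @export
fragmentAndAnchor <- function(target, model, config) {
  stopifnot(is(config, "SimConfig"), length(target) > 0L)
  unit <- config@geneLengthBp + config@intergenicBp
  rankOf <- stats::setNames(model$rank, model$gene_id)
  chromOf <- stats::setNames(model$chromosome, model$gene_id)

  # --- scaffold cutting (stage 3) ---
  set.seed(.stageSeed(config@seed, 3L))
  mu <- max(1, config@scaffoldN50Target / unit)
  scafRows <- list(); geneRows <- list()
  scafCounter <- 0L
  for (lg in names(target)) {
    genes <- target[[lg]]
    ng <- length(genes)
    pos <- 0L
    while (pos < ng) {
      k <- max(1L, stats::rpois(1L, mu))
      k <- min(k, ng - pos)
      scafCounter <- scafCounter + 1L
      sid <- sprintf("S%05d", scafCounter)
      j <- seq(pos + 1L, pos + k)
      starts <- (seq_len(k) - 1L) * unit + 1L
      scafRows[[scafCounter]] <- data.frame(
        scaffold_id = sid, length_bp = k * unit, linkage_group = lg,
        offset_bp = pos * unit, stringsAsFactors = FALSE)
      geneRows[[scafCounter]] <- data.frame(
        gene_id = genes[j], linkage_group = lg, scaffold_id = sid,
        start_bp = starts, end_bp = starts + config@geneLengthBp - 1L,
        model_chromosome = unname(chromOf[genes[j]]),
        model_rank = unname(rankOf[genes[j]]),
        target_order = j, stringsAsFactors = FALSE)
      pos <- pos + k
    }
  }
  scaffolds <- do.call(rbind, scafRows)
  targetGenes <- do.call(rbind, geneRows)
  rownames(scaffolds) <- rownames(targetGenes) <- NULL

  # --- markers and map positions (stage 4) ---
  set.seed(.stageSeed(config@seed, 4L))
  mkRows <- list(); mi <- 0L
  for (lg in names(target)) {
    lenBp <- length(target[[lg]]) * unit
    nMark <- max(1L, round(lenBp / 1e6 * config@markerDensityPerMb))
    posBp <- sort(stats::runif(nMark, 0, lenBp))
    cmRaw <- posBp / 1e6 * config@cmPerMb
    cm <- if (config@mapResolutionCm > 0)
      floor(cmRaw / config@mapResolutionCm) * config@mapResolutionCm else cmRaw
    ids <- sprintf("MK%05d", mi + seq_len(nMark))
    mkRows[[lg]] <- data.frame(
      marker_id = ids, linkage_group = lg, position_cm = cm,
      source_bac_id = sub("^MK", "BAC", ids),
      contig_id = sub("^MK", "CTG", ids), pos_bp = posBp,
      stringsAsFactors = FALSE)
    mi <- mi + nMark
  }
  markersFull <- do.call(rbind, mkRows)
  rownames(markersFull) <- NULL
  markers <- markersFull[, c("marker_id", "linkage_group", "position_cm",
                             "source_bac_id")]
  bacContig <- data.frame(bac_id = markersFull$source_bac_id,
                          contig_id = markersFull$contig_id,
                          stringsAsFactors = FALSE)

  # --- anchor sequences per scaffold (stage 5) ---
  set.seed(.stageSeed(config@seed, 5L))
  caRows <- list(); ssRows <- list(); ci <- 0L
  for (i in seq_len(nrow(scaffolds))) {
    if (stats::runif(1L) >= config@anchorEvidenceRate &&
        config@anchorEvidenceRate < 1) next
    lg <- scaffolds$linkage_group[[i]]
    mk <- markersFull[markersFull$linkage_group == lg, , drop = FALSE]
    lo <- scaffolds$offset_bp[[i]]; hi <- lo + scaffolds$length_bp[[i]]
    sel <- mk$pos_bp > lo & mk$pos_bp <= hi
    if (!any(sel)) {
      mid <- (lo + hi) / 2
      sel <- seq_len(nrow(mk)) == which.min(abs(mk$pos_bp - mid))
    }
    mk <- mk[sel, , drop = FALSE]
    kinds <- ifelse(stats::runif(nrow(mk)) < config@besFraction, "BES", "PMCSS")
    sid <- scaffolds$scaffold_id[[i]]
    asIds <- sprintf("AS_%s_%d", sid, seq_len(nrow(mk)))
    ci <- ci + 1L
    caRows[[ci]] <- data.frame(contig_id = mk$contig_id, anchor_seq_id = asIds,
                               anchor_seq_kind = kinds, stringsAsFactors = FALSE)
    ssRows[[ci]] <- data.frame(anchor_seq_id = asIds, scaffold_id = sid,
                               stringsAsFactors = FALSE)
  }
  contigAnchors <- if (ci) do.call(rbind, caRows) else
    data.frame(contig_id = character(), anchor_seq_id = character(),
               anchor_seq_kind = character(), stringsAsFactors = FALSE)
  seqScaffold <- if (ci) do.call(rbind, ssRows) else
    data.frame(anchor_seq_id = character(), scaffold_id = character(),
               stringsAsFactors = FALSE)
  rownames(contigAnchors) <- rownames(seqScaffold) <- NULL

  truthSegments <- .truthSegmentsFromLayout(targetGenes, model)
  list(targetGenes = targetGenes, scaffolds = scaffolds, markers = markers,
       bacContig = bacContig, contigAnchors = contigAnchors,
       seqScaffold = seqScaffold, truthSegments = truthSegments)
}

# Maximal consecutive-model-rank runs per (scaffold, model chromosome);
# genes listed by ascending model rank, matching the block detector's rule.
.truthSegmentsFromLayout <- function(targetGenes, model) {
  startOf <- stats::setNames(model$start_bp, model$gene_id)
  endOf <- stats::setNames(model$end_bp, model$gene_id)
  key <- paste(targetGenes$scaffold_id, targetGenes$model_chromosome, sep = "\r")
  groups <- split(seq_len(nrow(targetGenes)), key)
  segs <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    g <- targetGenes[idx, , drop = FALSE]
    g <- g[order(g$model_rank), , drop = FALSE]
    runid <- cumsum(c(1L, diff(g$model_rank) > 1L))
    do.call(rbind, lapply(split(seq_len(nrow(g)), runid), function(j) {
      gg <- g[j, , drop = FALSE]
      data.frame(
        scaffold_id = gg$scaffold_id[[1L]],
        linkage_group = gg$linkage_group[[1L]],
        model_chromosome = gg$model_chromosome[[1L]],
        gene_ids = paste(gg$gene_id, collapse = ";"),
        n_genes = nrow(gg),
        model_start_bp = min(startOf[gg$gene_id]),
        model_end_bp = max(endOf[gg$gene_id]),
        target_start_bp = min(gg$start_bp),
        target_end_bp = max(gg$end_bp),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, segs)
  out <- out[order(out$scaffold_id, out$model_chromosome, out$model_start_bp,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit a noisy protein-alignment hit table
#'
#' For every surviving target gene one true hit to its model gene is drawn
#' (e-value at most 1e-20, bitscore proportional to gene length). With
#' probability `paralogRate` a gene additionally receives a weaker hit
#' (strictly lower bitscore, e-value still under the usual 1e-10 cutoff) to
#' a random gene on the same model chromosome. With rate `spuriousHitRate`,
#' random scaffold intervals hit random genes with e-values in
#' (1e-10, 1e-2], so a 1e-10 filter removes all of them. The three hit
#' classes are drawn from independent sub-streams, so changing one rate
#' leaves the other classes' draws untouched.
#'
#' @param targetGenes,scaffolds from [fragmentAndAnchor()].
#' @param model model annotation.
#' @param config a [SimConfig-class].
#' @return hit data.frame (`query_id`, `query_start`, `query_end`,
#'   `subject_id`, `evalue`, `bitscore`, `class` in
#'   true/paralog/spurious).
#' @export
emitHitTable <- function(targetGenes, scaffolds, model, config) {
  stopifnot(is(config, "SimConfig"))
  n <- nrow(targetGenes)
  set.seed(.stageSeed(config@seed, 6L))
  glen <- targetGenes$end_bp - targetGenes$start_bp + 1L
  true <- data.frame(
    query_id = targetGenes$scaffold_id,
    query_start = targetGenes$start_bp,
    query_end = targetGenes$end_bp,
    subject_id = targetGenes$gene_id,
    evalue = 10^-stats::runif(n, 20, 180),
    bitscore = round(glen * 1.8 * stats::runif(n, 0.95, 1.05), 1),
    class = "true", stringsAsFactors = FALSE)

  paralog <- true[0, , drop = FALSE]
  if (config@paralogRate > 0) {
    set.seed(.stageSeed(config@seed, 7L))
    sel <- which(stats::runif(n) < config@paralogRate)
    if (length(sel)) {
      byChrom <- split(model$gene_id, model$chromosome)
      subj <- vapply(sel, function(i) {
        cand <- setdiff(byChrom[[targetGenes$model_chromosome[[i]]]],
                        targetGenes$gene_id[[i]])
        if (length(cand)) .resample(cand, 1L) else NA_character_
      }, character(1))
      ok <- !is.na(subj)
      sel <- sel[ok]; subj <- subj[ok]
      if (length(sel)) {
        paralog <- data.frame(
          query_id = targetGenes$scaffold_id[sel],
          query_start = targetGenes$start_bp[sel],
          query_end = targetGenes$end_bp[sel],
          subject_id = subj,
          evalue = 10^-stats::runif(length(sel), 10.5, 14),
          bitscore = round(true$bitscore[sel] *
                             stats::runif(length(sel), 0.4, 0.8), 1),
          class = "paralog", stringsAsFactors = FALSE)
      }
    }
  }

  spurious <- true[0, , drop = FALSE]
  if (config@spuriousHitRate > 0) {
    set.seed(.stageSeed(config@seed, 8L))
    ns <- stats::rbinom(1L, n, config@spuriousHitRate)
    if (ns > 0L) {
      si <- sample.int(nrow(scaffolds), ns, replace = TRUE)
      slen <- scaffolds$length_bp[si]
      qs <- pmax(1L, as.integer(stats::runif(ns, 1, pmax(2, slen - 200))))
      qe <- pmin(slen, qs + as.integer(stats::runif(ns, 100, 1000)))
      spurious <- data.frame(
        query_id = scaffolds$scaffold_id[si],
        query_start = qs, query_end = qe,
        subject_id = model$gene_id[sample.int(nrow(model), ns, replace = TRUE)],
        evalue = 10^-stats::runif(ns, 2, 10),
        bitscore = round(stats::runif(ns, 30, 60), 1),
        class = "spurious", stringsAsFactors = FALSE)
    }
  }
  out <- rbind(true, paralog, spurious)
  rownames(out) <- NULL
  out
}

#' Run the full comparative-genome simulation
#'
#' Convenience wrapper chaining [simulateModelGenome()],
#' [applyRearrangements()], [fragmentAndAnchor()] and [emitHitTable()] into
#' a single ground-truthed [SynMapSim-class] bundle.
#'
#' @param config a [SimConfig-class].
#' @return a [SynMapSim-class] object.
#' @examples
#' sim <- simulateComparativeGenomes(
#'   simConfig(seed = 7, nChromosomes = 4, genesPerChromosome = 30,
#'             nFusions = 1, nFissions = 1, nInversions = 1,
#'             nTranslocations = 1))
#' sim
#' @export
simulateComparativeGenomes <- function(config = simConfig()) {
  model <- simulateModelGenome(config)
  rearr <- applyRearrangements(model, config)
  frag <- fragmentAndAnchor(rearr$target, model, config)
  hits <- emitHitTable(frag$targetGenes, frag$scaffolds, model, config)
  new("SynMapSim", config = config, modelGenes = model,
      targetGenes = frag$targetGenes, scaffolds = frag$scaffolds,
      markers = frag$markers, bacContig = frag$bacContig,
      contigAnchors = frag$contigAnchors, seqScaffold = frag$seqScaffold,
      hits = hits, truthSegments = frag$truthSegments,
      eventLog = rearr$eventLog)
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' Serializes every table of a [SynMapSim-class]: linkage map, scaffold
#' index, physical-map membership, anchor-sequence and match tables (header
#' TSV), the model annotation (BED), the hit table (12-column BLAST
#' tabular), plus the ground-truth files (truth segments, event log, target
#' gene layout) and the configuration (YAML). Identical configurations
#' produce byte-identical files.
#'
#' @param sim a [SynMapSim-class].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "SynMapSim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeLinkageMap(markerTable(sim), p("linkage_map.tsv"))
  .writeTsv(scaffoldIndex(sim)[, c("scaffold_id", "length_bp")],
            p("scaffolds.tsv"))
  ev <- evidenceTables(sim)
  .writeTsv(ev$bacContig, p("bac_contig.tsv"))
  .writeTsv(ev$contigAnchors, p("contig_anchor_seqs.tsv"))
  .writeTsv(ev$seqScaffold, p("seq_scaffold_matches.tsv"))
  writeGeneAnnotation(modelAnnotation(sim), p("model_genes.bed"))
  writeHitTable(hitTable(sim), p("hits.tsv"))
  .writeTsv(truthSegments(sim), p("truth_segments.tsv"))
  .writeTsv(eventLog(sim), p("event_log.tsv"))
  .writeTsv(targetGenes(sim), p("target_genes.tsv"))
  cfg <- simulationConfig(sim)
  cfgList <- stats::setNames(lapply(slotNames(cfg), function(s) slot(cfg, s)),
                             slotNames(cfg))
  yaml::write_yaml(cfgList, p("sim_config.yaml"))
  invisible(stats::setNames(
    file.path(dir, c("linkage_map.tsv", "scaffolds.tsv", "bac_contig.tsv",
                     "contig_anchor_seqs.tsv", "seq_scaffold_matches.tsv",
                     "model_genes.bed", "hits.tsv", "truth_segments.tsv",
                     "event_log.tsv", "target_genes.tsv", "sim_config.yaml")),
    c("linkage_map", "scaffolds", "bac_contig", "contig_anchor_seqs",
      "seq_scaffold_matches", "model_genes", "hits", "truth_segments",
      "event_log", "target_genes", "sim_config")))
}
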