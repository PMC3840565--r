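# Rendering and orchestration: Oxford-grid export (TSV + optional
# two-colour image), MapChart-dialect comparative map text, and the
# end-to-end pipeline driver with a reproducibility manifest.

#' Export an Oxford grid
#'
#' Writes the gene-sharing matrix as a header TSV with integer percentage
#' cells (rounded half-up, the conventional display precision for such
#' grids; full precision stays in the [HomologyMatrix-class] object).
#' Optionally renders a PNG in the customary two-colour highlighting:
#' cells strictly above the highlight threshold in yellow, cells between
#' the segment and highlight thresholds in orange.
#'
#' @param matrix a [HomologyMatrix-class].
#' @param file output TSV path.
#' @param config a [ChromoMapConfig-class] (thresholds for the colouring).
#' @param image optional PNG path; no image is produced when `NULL`.
#' @return `file`, invisibly.
#' @export
exportOxfordGrid <- function(matrix, file, config = chromoMapConfig(),
                             image = NULL) {
  stopifnot(is(matrix, "HomologyMatrix"))
  m <- roundHalfUp(matrix@pct)
  df <- data.frame(linkage_group = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, file)
  if (!is.null(image)) {
    pct <- matrix@pct
    grDevices::png(image, width = 140 + 28 * ncol(pct),
                   height = 60 + 22 * nrow(pct))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 5, 3, 1))
    graphics::plot(NULL, xlim = c(0, ncol(pct)), ylim = c(0, nrow(pct)),
                   axes = FALSE, xlab = "", ylab = "", asp = NA)
    for (i in seq_len(nrow(pct))) for (j in seq_len(ncol(pct))) {
      v <- pct[i, j]
      col <- if (v > config@highlightThresholdPct) "gold"
             else if (v > config@segmentThresholdPct) "orange"
             else "white"
      graphics::rect(j - 1, nrow(pct) - i, j, nrow(pct) - i + 1,
                     col = col, border = "grey70")
      if (v > 0)
        graphics::text(j - 0.5, nrow(pct) - i + 0.5, roundHalfUp(v),
                       cex = 0.7)
    }
    graphics::axis(2, at = seq_len(nrow(pct)) - 0.5,
                   labels = rev(rownames(pct)), las = 2, tick = FALSE,
                   cex.axis = 0.7)
    graphics::axis(3, at = seq_len(ncol(pct)) - 0.5, labels = colnames(pct),
                   las = 2, tick = FALSE, cex.axis = 0.7)
  }
  invisible(file)
}

#' @rdname exportOxfordGrid
#' @return `readOxfordGrid()`: the rendered integer matrix (linkage groups
#'   as row names).
#' @export
readOxfordGrid <- function(file) {
  df <- utils::read.delim(file, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Export a MapChart comparative map
#'
#' Writes the minimal MapChart plain-text dialect: a `group` header line
#' followed by `name position` rows, positions in the unit of the section.
#' Three sections are emitted for the chosen linkage group: the markers at
#' their cM positions, the anchored scaffolds at their cM positions
#' (scaffolds stacked at one cM ordered by scaffold id), and the
#' homologous model chromosome's genes at Mb positions (three decimals).
#'
#' @param markers linkage-map data.frame.
#' @param lgAssignments assignments with linkage groups
#'   ([homologsPerLinkageGroup()]).
#' @param lg linkage group to export.
#' @param file output path.
#' @param modelChromosome model chromosome for the right-hand section;
#'   defaults to the chromosome holding the most of the LG's placed
#'   homologs.
#' @return `file`, invisibly.
#' @export
exportMapChart <- function(markers, lgAssignments, lg, file,
                           modelChromosome = NULL) {
  valid <- .naturalSort(unique(c(markers$linkage_group,
                                 lgAssignments$linkage_group)))
  if (!lg %in% valid)
    .stopf("unknown linkage group '%s'; valid groups: %s", lg,
           paste(valid, collapse = ", "))
  out <- character()
  mk <- markers[markers$linkage_group == lg, , drop = FALSE]
  mk <- mk[order(mk$position_cm, mk$marker_id, method = "radix"), ,
           drop = FALSE]
  out <- c(out, sprintf("group %s", lg),
           sprintf("%s %s", mk$marker_id, formatC(mk$position_cm,
                                                  format = "fg")))
  a <- lgAssignments[lgAssignments$linkage_group == lg, , drop = FALSE]
  scaf <- unique(a[, c("scaffold_id", "position_cm")])
  if (nrow(scaf)) {
    scaf <- scaf[order(scaf$position_cm, scaf$scaffold_id,
                       method = "radix"), , drop = FALSE]
    out <- c(out, "", sprintf("group %s_scaffolds", lg),
             sprintf("%s %s", scaf$scaffold_id,
                     formatC(scaf$position_cm, format = "fg")))
  }
  ap <- a[a$placed, , drop = FALSE]
  if (nrow(ap)) {
    if (is.null(modelChromosome)) {
      tab <- sort(table(unique(ap[, c("gene_id", "chromosome")])$chromosome),
                  decreasing = TRUE)
      modelChromosome <- names(tab)[[1L]]
    }
    g <- unique(ap[ap$chromosome == modelChromosome,
                   c("gene_id", "gene_start_bp")])
    g <- g[order(g$gene_start_bp, g$gene_id, method = "radix"), ,
           drop = FALSE]
    out <- c(out, "", sprintf("group %s", modelChromosome),
             sprintf("%s %.3f", g$gene_id, g$gene_start_bp / 1e6))
  }
  writeLines(out, file)
  invisible(file)
}

#' Run the whole comparative-mapping pipeline
#'
#' Executes simulate (optional) -> anchor -> homologs -> Oxford grid ->
#' synteny -> report in order, writing every stage's table to `outdir`
#' along with a reproducibility manifest (inputs, configuration hash, seed,
#' and per-output row counts). The configuration is a YAML file (or an
#' equivalent named list) with sections `simulate` (SimConfig fields,
#' snake_case) or `inputs` (paths: `linkage_map`, `scaffolds`,
#' `bac_contig`, `contig_anchor_seqs`, `seq_scaffold_matches`,
#' `annotation`, `hits`, `species`), plus optional `homology`, `chromomap`,
#' `synteny` sections mirroring the config objects, and `output: dir`.
#' Configuration problems are raised before any stage runs; a stage
#' failure is reported with the stage name and cause.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @param outdir output directory (overrides `output: dir`).
#' @param seed optional integer overriding `simulate: seed`.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) .stopf("configuration error: file not found: %s", config)
    yaml::read_yaml(config)
  } else config
  if (!is.list(cfg)) .stopf("configuration error: config must be a YAML file or list")
  outdir <- outdir %||% cfg$output$dir
  if (is.null(outdir)) .stopf("configuration error: no output directory given")
  simulateMode <- !is.null(cfg$simulate)
  if (!simulateMode) {
    need <- c("linkage_map", "scaffolds", "bac_contig", "contig_anchor_seqs",
              "seq_scaffold_matches", "annotation", "hits")
    for (k in need) {
      if (is.null(cfg$inputs[[k]]))
        .stopf("configuration error: missing input path '%s'", k)
      if (!file.exists(cfg$inputs[[k]]))
        .stopf("configuration error: input '%s' not found: %s", k,
               cfg$inputs[[k]])
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  section <- function(x) {
    if (is.null(x) || !length(x)) return(list())
    names(x) <- .snakeToCamel(names(x))
    x
  }
  hcfg <- do.call(homologyConfig, section(cfg$homology))
  ccfg <- do.call(chromoMapConfig, section(cfg$chromomap))
  scfg <- do.call(syntenyConfig, section(cfg$synteny))

  sim <- NULL
  if (simulateMode) {
    simArgs <- cfg$simulate
    if (!is.null(seed)) simArgs$seed <- seed
    names(simArgs) <- .snakeToCamel(names(simArgs))
    sim <- stage("simulate", simulateComparativeGenomes(
      do.call(simConfig, simArgs)))
    markers <- markerTable(sim)
    scaffolds <- scaffoldIndex(sim)[, c("scaffold_id", "length_bp")]
    ev <- evidenceTables(sim)
    bacContig <- ev$bacContig
    contigAnchors <- ev$contigAnchors
    seqScaffold <- ev$seqScaffold
    annotation <- modelAnnotation(sim)
    hits <- hitTable(sim)[, c("query_id", "query_start", "query_end",
                              "subject_id", "evalue", "bitscore")]
    species <- "model"
  } else {
    markers <- stage("read", readLinkageMap(cfg$inputs$linkage_map))
    scaffolds <- stage("read", readScaffoldIndex(cfg$inputs$scaffolds))
    bacContig <- stage("read", readMembershipTable(cfg$inputs$bac_contig))
    contigAnchors <- stage("read", readAnchorSeqTable(cfg$inputs$contig_anchor_seqs))
    seqScaffold <- stage("read", readMatchTable(cfg$inputs$seq_scaffold_matches))
    species <- cfg$inputs$species %||% "model"
    annotation <- stage("read", readGeneAnnotation(cfg$inputs$annotation, species))
    hits <- stage("read", readHitTable(cfg$inputs$hits))
  }

  anchoredSet <- stage("anchor", buildEvidenceChains(
    markers, bacContig, contigAnchors, seqScaffold, scaffolds = scaffolds))
  stats <- stage("anchor", computeAnchorStats(scaffolds, anchoredSet))
  filtered <- stage("homologs", filterHits(hits, hcfg))
  assignments <- stage("homologs", assignBestHits(filtered, annotation, hcfg))
  lgAssign <- stage("homologs", homologsPerLinkageGroup(assignments, anchoredSet))
  lgCounts <- stage("homologs", countHomologsPerLG(lgAssign))
  mat <- stage("chromomap", buildHomologyMatrix(lgAssign, species = species))
  classes <- stage("chromomap", classifyRelationships(mat, ccfg))
  events <- stage("chromomap", detectFusionFission(mat, config = ccfg))
  blocks <- stage("synteny", detectSyntenyBlocks(lgAssign, annotation, scfg))
  blockSummary <- stage("synteny", summarizeBlocks(blocks))

  outputs <- list(
    anchored_scaffolds.tsv = anchoredScaffolds(anchoredSet),
    anchor_stats.tsv = as.data.frame(stats),
    assignments.tsv = lgAssign,
    lg_homolog_counts.tsv = lgCounts,
    homology_matrix.tsv = NULL,  # written by exportOxfordGrid below
    chromosome_classes.tsv = classes,
    chromosome_events.tsv = events,
    synteny_blocks.tsv = blocks,
    block_summary.tsv = formatBlockSummary(blockSummary))
  stage("report", exportOxfordGrid(mat, file.path(outdir, "homology_matrix.tsv"),
                                   ccfg))
  for (f in names(outputs)) {
    if (!is.null(outputs[[f]])) .writeTsv(outputs[[f]], file.path(outdir, f))
  }
  rowCounts <- vapply(names(outputs), function(f) {
    if (is.null(outputs[[f]]))
      nrow(sharingPct(mat)) else nrow(outputs[[f]])
  }, integer(1))

  cfgPath <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(cfg, cfgPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("synmapr")),
    mode = if (simulateMode) "simulate" else "files",
    seed = if (simulateMode) (if (!is.null(seed)) seed else
      cfg$simulate$seed %||% 1L) else NULL,
    config_hash = unname(tools::md5sum(cfgPath)),
    inputs = if (simulateMode) "simulated" else
      lapply(cfg$inputs, function(p) if (is.character(p) && file.exists(p))
        unname(tools::md5sum(p)) else p),
    row_counts = as.list(rowCounts))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, anchoredSet = anchoredSet, anchorStats = stats,
                 assignments = lgAssign, lgCounts = lgCounts, matrix = mat,
                 classes = classes, events = events, blocks = blocks,
                 blockSummary = blockSummary, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.snakeToCamel <- function(x) {
  vapply(strsplit(x, "_", fixed = TRUE), function(p) {
    if (length(p) == 1L) return(p)
    paste0(p[[1L]], paste0(toupper(substring(p[-1L], 1L, 1L)),
                           substring(p[-1L], 2L), collapse = ""))
  }, character(1))
}
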