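# Readers and writers for the tabular dialects the pipeline touches:
# header TSV for markers / physical-map membership / anchor sequences /
# scaffold index, 12-column headerless BLAST tabular (outfmt 6) for hits,
# and 4-column BED for gene annotation. All readers have a strict mode
# (default; malformed rows are errors naming the offending line) and a
# lenient mode (bad rows skipped with a warning).

#' Read a linkage-map marker table
#'
#' Expects a tab-separated file with header columns `marker_id`,
#' `linkage_group`, `position_cm`, `source_bac_id`. Markers are sorted by
#' (linkage group, cM position, marker id) on return; duplicate marker ids
#' are rejected.
#'
#' @param path file path.
#' @param strict logical; if `TRUE` (default) malformed rows and duplicate
#'   marker ids are errors, otherwise they are skipped with a warning.
#' @return data.frame of markers.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("marker_id\tlinkage_group\tposition_cm\tsource_bac_id",
#'              "m2\tLG1\t5.2\tbacB", "m1\tLG1\t0.0\tbacA"), f)
#' readLinkageMap(f)
#' @export
readLinkageMap <- function(path, strict = TRUE) {
  df <- .readTsv(path, "linkage map")
  .checkColumns(df, c("marker_id", "linkage_group", "position_cm",
                      "source_bac_id"), "linkage map")
  cm <- .parseNumericColumn(df$position_cm, "cM position", "linkage map", strict)
  df$position_cm <- cm$values
  if (length(cm$bad)) df <- df[-cm$bad, , drop = FALSE]
  if (nrow(df) && any(df$position_cm < 0))
    .stopf("linkage map: negative cM position for marker '%s'",
           df$marker_id[df$position_cm < 0][[1L]])
  if (nrow(df) && any(!nzchar(df$source_bac_id)))
    .stopf("linkage map: empty source_bac_id for marker '%s'",
           df$marker_id[!nzchar(df$source_bac_id)][[1L]])
  dup <- duplicated(df$marker_id)
  if (any(dup)) {
    if (strict)
      .stopf("linkage map: duplicate marker_id '%s'", df$marker_id[dup][[1L]])
    .warnf("linkage map: dropping %d duplicate marker row(s)", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$linkage_group, df$position_cm, df$marker_id,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("marker_id", "linkage_group", "position_cm", "source_bac_id")]
}

#' @rdname readLinkageMap
#' @param markers data.frame as returned by `readLinkageMap()`.
#' @export
writeLinkageMap <- function(markers, path) {
  .checkColumns(markers, c("marker_id", "linkage_group", "position_cm",
                           "source_bac_id"), "linkage map")
  .writeTsv(markers, path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the 12-column headerless tab-separated alignment dialect (query,
#' subject, identity, length, mismatches, gaps, qstart, qend, sstart, send,
#' evalue, bitscore). Query coordinates are normalized so that
#' `query_start <= query_end`; reading-frame orientation is discarded.
#'
#' @param path file path.
#' @param strict logical; malformed rows are errors naming the line number
#'   when `TRUE` (default), otherwise skipped with a warning.
#' @return data.frame with columns `query_id`, `query_start`, `query_end`,
#'   `subject_id`, `evalue`, `bitscore`.
#' @export
readHitTable <- function(path, strict = TRUE) {
  if (!file.exists(path)) .stopf("hit table: file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.emptyHits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad)) {
    if (strict)
      .stopf("hit table: line %d: expected 12 tab-separated columns, found %d",
             bad[[1L]], nf[bad[[1L]]])
    .warnf("hit table: skipping %d row(s) with wrong column count", length(bad))
    parts <- parts[-bad]
    if (!length(parts)) return(.emptyHits())
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    nb <- which(is.na(v))
    if (length(nb)) {
      ln <- if (length(bad)) setdiff(seq_along(nf), bad)[nb[[1L]]] else nb[[1L]]
      if (strict)
        .stopf("hit table: line %d: unparseable %s '%s'", ln, what, m[nb[[1L]], j])
    }
    list(v = v, bad = nb)
  }
  qs <- num(7L, "qstart"); qe <- num(8L, "qend")
  ev <- num(11L, "e-value"); bs <- num(12L, "bitscore")
  drop <- sort(unique(c(qs$bad, qe$bad, ev$bad, bs$bad)))
  keep <- setdiff(seq_len(nrow(m)), drop)
  if (length(drop))
    .warnf("hit table: skipping %d unparseable row(s)", length(drop))
  if (any(ev$v[keep] < 0))
    .stopf("hit table: negative e-value for query '%s'",
           m[keep, 1L][ev$v[keep] < 0][[1L]])
  df <- data.frame(
    query_id = m[keep, 1L],
    query_start = as.integer(pmin(qs$v[keep], qe$v[keep])),
    query_end = as.integer(pmax(qs$v[keep], qe$v[keep])),
    subject_id = m[keep, 2L],
    evalue = ev$v[keep],
    bitscore = bs$v[keep],
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.emptyHits <- function() {
  data.frame(query_id = character(), query_start = integer(),
             query_end = integer(), subject_id = character(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname readHitTable
#' @param hits data.frame of hit records.
#' @export
writeHitTable <- function(hits, path) {
  .checkColumns(hits, c("query_id", "query_start", "query_end", "subject_id",
                        "evalue", "bitscore"), "hit table")
  alen <- hits$query_end - hits$query_start + 1L
  out <- cbind(hits$query_id, hits$subject_id, "100.00", alen, 0L, 0L,
               hits$query_start, hits$query_end, 1L, alen,
               format(hits$evalue, digits = 15, scientific = TRUE, trim = TRUE),
               format(hits$bitscore, digits = 15, trim = TRUE))
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Reads a headerless tab-separated BED file (chromosome, start, end,
#' gene id; 0-based half-open) and converts to 1-based inclusive
#' coordinates. Per-chromosome gene ranks are assigned by ascending start
#' position with ties broken by gene id; genes on the reserved `UNPLACED`
#' chromosome receive no rank and never enter rank-based adjacency.
#'
#' @param path file path.
#' @param species character label stored with every gene.
#' @param strict logical; malformed rows are errors when `TRUE` (default).
#' @return data.frame with columns `species`, `gene_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `rank` (NA for unplaced genes).
#' @export
readGeneAnnotation <- function(path, species, strict = TRUE) {
  if (!file.exists(path)) .stopf("gene annotation: file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!nrow(df)) return(assignGeneRanks(.emptyGenes(species)))
  if (ncol(df) < 4L)
    .stopf("gene annotation: expected >= 4 BED columns, found %d", ncol(df))
  st <- .parseNumericColumn(df[[2L]], "start", "gene annotation", strict, 0L)
  en <- .parseNumericColumn(df[[3L]], "end", "gene annotation", strict, 0L)
  drop <- sort(unique(c(st$bad, en$bad)))
  keep <- setdiff(seq_len(nrow(df)), drop)
  genes <- data.frame(
    species = species,
    gene_id = df[[4L]][keep],
    chromosome = df[[1L]][keep],
    start_bp = as.integer(st$values[keep]) + 1L,  # BED 0-based -> 1-based
    end_bp = as.integer(en$values[keep]),
    stringsAsFactors = FALSE)
  bad <- which(genes$start_bp > genes$end_bp)
  if (length(bad)) {
    if (strict)
      .stopf("gene annotation: line %d: start > end after coordinate conversion (gene '%s')",
             keep[bad[[1L]]], genes$gene_id[bad[[1L]]])
    .warnf("gene annotation: dropping %d row(s) with start > end", length(bad))
    genes <- genes[-bad, , drop = FALSE]
  }
  assignGeneRanks(genes)
}

.emptyGenes <- function(species = character()) {
  data.frame(species = species[0], gene_id = character(),
             chromosome = character(), start_bp = integer(),
             end_bp = integer(), stringsAsFactors = FALSE)
}

#' Assign per-chromosome gene ranks
#'
#' Orders genes within each (species, chromosome) by ascending start
#' position (ties broken by gene id) and assigns ranks 1..n. Genes on the
#' `UNPLACED` chromosome get `NA`.
#'
#' @param genes data.frame with at least `species`, `gene_id`,
#'   `chromosome`, `start_bp`, `end_bp`.
#' @return the same data.frame, row-sorted by (species, chromosome, rank),
#'   with a `rank` column.
#' @export
assignGeneRanks <- function(genes) {
  .checkColumns(genes, c("species", "gene_id", "chromosome", "start_bp",
                         "end_bp"), "gene table")
  if (!nrow(genes)) {
    genes$rank <- integer()
    return(genes)
  }
  o <- order(genes$species, genes$chromosome, genes$start_bp, genes$gene_id,
             method = "radix")
  genes <- genes[o, , drop = FALSE]
  key <- paste(genes$species, genes$chromosome, sep = "\r")
  genes$rank <- stats::ave(seq_len(nrow(genes)), key, FUN = seq_along)
  genes$rank[genes$chromosome == UNPLACED] <- NA_integer_
  rownames(genes) <- NULL
  genes
}

#' @rdname readGeneAnnotation
#' @param genes data.frame of gene loci (1-based inclusive coordinates).
#' @export
writeGeneAnnotation <- function(genes, path) {
  .checkColumns(genes, c("gene_id", "chromosome", "start_bp", "end_bp"),
                "gene annotation")
  bed <- data.frame(genes$chromosome, genes$start_bp - 1L, genes$end_bp,
                    genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read simple evidence tables
#'
#' Header-TSV readers for the remaining pipeline inputs: the scaffold index
#' (`scaffold_id`, `length_bp`), the physical-map membership table
#' (`bac_id`, `contig_id`), the contig anchor-sequence table (`contig_id`,
#' `anchor_seq_id`, `anchor_seq_kind` with kind `BES` or `PMCSS`), and the
#' anchor-sequence-to-scaffold match table (`anchor_seq_id`,
#' `scaffold_id`).
#'
#' @param path file path.
#' @param strict logical; malformed rows are errors when `TRUE`.
#' @return a data.frame with the columns listed above.
#' @export
readScaffoldIndex <- function(path, strict = TRUE) {
  df <- .readTsv(path, "scaffold index")
  .checkColumns(df, c("scaffold_id", "length_bp"), "scaffold index")
  lb <- .parseNumericColumn(df$length_bp, "length_bp", "scaffold index", strict)
  df$length_bp <- as.integer(lb$values)
  if (length(lb$bad)) df <- df[-lb$bad, , drop = FALSE]
  if (nrow(df) && any(df$length_bp <= 0, na.rm = TRUE))
    .stopf("scaffold index: non-positive length for scaffold '%s'",
           df$scaffold_id[df$length_bp <= 0][[1L]])
  if (anyDuplicated(df$scaffold_id))
    .stopf("scaffold index: duplicate scaffold_id '%s'",
           df$scaffold_id[duplicated(df$scaffold_id)][[1L]])
  rownames(df) <- NULL
  df[, c("scaffold_id", "length_bp")]
}

#' @rdname readScaffoldIndex
#' @export
readMembershipTable <- function(path, strict = TRUE) {
  df <- .readTsv(path, "physical-map membership")
  .checkColumns(df, c("bac_id", "contig_id"), "physical-map membership")
  df[, c("bac_id", "contig_id")]
}

#' @rdname readScaffoldIndex
#' @export
readAnchorSeqTable <- function(path, strict = TRUE) {
  df <- .readTsv(path, "anchor-sequence table")
  .checkColumns(df, c("contig_id", "anchor_seq_id", "anchor_seq_kind"),
                "anchor-sequence table")
  bad <- !df$anchor_seq_kind %in% c("BES", "PMCSS")
  if (any(bad)) {
    if (strict)
      .stopf("anchor-sequence table: invalid anchor_seq_kind '%s' (expected BES or PMCSS)",
             df$anchor_seq_kind[bad][[1L]])
    .warnf("anchor-sequence table: dropping %d row(s) with invalid kind", sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("contig_id", "anchor_seq_id", "anchor_seq_kind")]
}

#' @rdname readScaffoldIndex
#' @export
readMatchTable <- function(path, strict = TRUE) {
  df <- .readTsv(path, "anchor-to-scaffold match table")
  .checkColumns(df, c("anchor_seq_id", "scaffold_id"),
                "anchor-to-scaffold match table")
  df[, c("anchor_seq_id", "scaffold_id")]
}

#' @rdname readScaffoldIndex
#' @param df data.frame to serialize as header TSV.
#' @export
writeTable <- function(df, path) .writeTsv(df, path)
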