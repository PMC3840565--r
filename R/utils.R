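#' Round half away from zero
#'
#' Rendering helper matching the integer display convention of Oxford-grid
#' percentages and table summaries (0.5 always rounds up, unlike [round()]'s
#' round-half-even).
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

# Reserved chromosome token for genes without a chromosome assignment.
UNPLACED <- "UNPLACED"

.checkColumns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stopf("%s: missing required column '%s'", what, miss[[1L]])
  invisible(df)
}

# Natural sort for chromosome / linkage-group labels: shared alphabetic
# prefix first, then numeric suffix ("LG2" < "LG10", "chr2" < "chr10").
.naturalOrder <- function(x) {
  pre <- sub("([0-9]+)$", "", x)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", x)))
  num[!grepl("[0-9]$", x)] <- NA
  order(pre, num, x, method = "radix", na.last = TRUE)
}

.naturalSort <- function(x) x[.naturalOrder(x)]

# Deterministic sub-seed for an internally seeded simulation stage. Stages
# draw from independent streams so that changing one stage's rate parameters
# cannot perturb another stage's draws.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1013L + 7L * as.integer(stage)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, what) {
  if (!file.exists(path)) .stopf("%s: file not found: %s", what, path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.parseNumericColumn <- function(x, col, what, strict, offset = 1L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) | is.na(x))
  if (length(bad)) {
    if (strict)
      .stopf("%s: line %d: non-numeric %s '%s'", what, bad[[1L]] + offset,
             col, x[bad[[1L]]])
    .warnf("%s: dropping %d row(s) with non-numeric %s", what, length(bad), col)
  }
  list(values = v, bad = bad)
}
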