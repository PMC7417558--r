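# Parsing and writing of tabular homology-hit files.
#
# Two dialects are supported: "primary" is the 12-column NT-style layout
#   qseqid sseqid length pident gaps sstart send qcovs evalue bitscore
#   staxids stitle
# and "fallback" is the 10-column layout of the second database (same first
# ten columns, no staxids/stitle); its taxon names are carried in sseqid.

.dialectCols <- function(dialect) {
  if (dialect == "primary") 12L else 10L
}

#' Parse a tabular homology-hit file
#'
#' Reads a tab-separated hit table in one of the two supported dialects and
#' splits it per query, preserving the input hit order within each query.
#' Fallback-dialect hits get empty `staxids`/`stitle`; their genus/species
#' are later parsed from `sseqid`.
#'
#' @param x path to a TSV file, or a character vector of already-read lines.
#' @param dialect `"primary"` (12 columns) or `"fallback"` (10 columns).
#' @return Named list, one data.frame of hits per `qseqid`, in order of
#'   first appearance; each data.frame carries a `dialect` attribute.
#' @examples
#' line <- paste("OTU_1", "ACC000001.1", 300, 99.1, 0, 1, 300, 100,
#'               1e-50, 550, "12345", "Fictoceras simulans COI", sep = "\t")
#' parseHitTable(line, "primary")
#' @export
parseHitTable <- function(x, dialect = c("primary", "fallback")) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(lines)]
  want <- .dialectCols(dialect)
  if (!length(lines)) return(structure(list(), dialect = dialect))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != want))
    stop("expected ", want, " tab-separated columns (", dialect,
         " dialect) but found ", nc[nc != want][1], " at line ",
         which(nc != want)[1])
  m <- do.call(rbind, parts)
  numCols <- 3:10
  numNames <- c("length", "pident", "gaps", "sstart", "send", "qcovs",
                "evalue", "bitscore")
  nums <- suppressWarnings(apply(m[, numCols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = 8)
  if (anyNA(nums)) {
    bad <- which(rowSums(is.na(nums)) > 0)[1]
    stop("unparseable numeric field at line ", bad)
  }
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (k in seq_along(numNames)) df[[numNames[k]]] <- nums[, k]
  df$staxids <- if (want == 12L) m[, 11] else ""
  df$stitle <- if (want == 12L) m[, 12] else ""
  df <- df[, .hitColumns]
  if (any(df$pident < 0 | df$pident > 100))
    stop("pident out of [0, 100]")
  if (any(df$qcovs < 0 | df$qcovs > 100))
    stop("qcovs out of [0, 100]")
  if (any(df$evalue < 0) || any(df$length < 0))
    stop("negative evalue or alignment length")
  out <- split(df, factor(df$qseqid, levels = unique(df$qseqid)))
  out <- lapply(out, function(d) {
    rownames(d) <- NULL
    attr(d, "dialect") <- dialect
    d
  })
  structure(out, dialect = dialect)
}

#' Write hits to a tabular TSV file
#'
#' @param hits data.frame in the 12-column order (e.g. from
#'   [genHitTable()]`$hits`).
#' @param path output file.
#' @param dialect `"primary"` writes all 12 columns, `"fallback"` the first
#'   10.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path, dialect = c("primary", "fallback")) {
  dialect <- match.arg(dialect)
  cols <- .hitColumns[seq_len(.dialectCols(dialect))]
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# First two purely alphabetic tokens of a free-text subject title; used as
# genus and species epithet for the primary dialect.
.taxonFromTitle <- function(stitle) {
  toks <- strsplit(stitle, "[^A-Za-z]+")
  t(vapply(toks, function(tt) {
    tt <- tt[nzchar(tt)]
    if (length(tt) >= 2L)
      c(tt[1], paste(tt[1], tolower(tt[2])))
    else if (length(tt) == 1L) c(tt[1], NA_character_)
    else c(NA_character_, NA_character_)
  }, character(2)))
}

# Fallback dialect: genus/species from sseqid fields split on "|" or "_".
.taxonFromSseqid <- function(sseqid) {
  toks <- strsplit(sseqid, "[|_]")
  t(vapply(toks, function(tt) {
    tt <- tt[grepl("^[A-Za-z]+$", tt)]
    if (length(tt) >= 2L)
      c(tt[1], paste(tt[1], tolower(tt[2])))
    else if (length(tt) == 1L) c(tt[1], NA_character_)
    else c(NA_character_, NA_character_)
  }, character(2)))
}

# genus/species columns for a hit frame under a dialect
hitTaxon <- function(hits, dialect) {
  if (!nrow(hits))
    return(data.frame(genus = character(0), species = character(0),
                      stringsAsFactors = FALSE))
  m <- if (dialect == "primary") .taxonFromTitle(hits$stitle)
       else .taxonFromSseqid(hits$sseqid)
  data.frame(genus = m[, 1], species = m[, 2], stringsAsFactors = FALSE)
}
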