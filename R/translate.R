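# Six-frame translation under multiple NCBI genetic codes, for validating
# COI OTUs as plausible protein-coding barcodes (pseudogene/NUMT screening).

.iupacRe <- "^[ACGTRYSWKMBDHVN]*$"

#' Translate a sequence in all six frames under several genetic codes
#'
#' Frames +1, +2, +3 read the sequence as given; -1, -2, -3 read its
#' reverse complement. Trailing partial codons are ignored. Codons
#' containing IUPAC ambiguity codes translate to `X` and never count as
#' stops. The default code set \{1, 2, 4, 5, 9\} covers the standard code
#' plus the mitochondrial tables common in marine metazoans.
#'
#' @param seq DNA string, length >= 3, IUPAC letters only.
#' @param codes NCBI genetic-code table numbers (non-empty).
#' @return data.frame with one row per (frame, code), frames major in the
#'   order +1, +2, +3, -1, -2, -3: columns `frame`, `genetic_code_id`,
#'   `protein`, `has_internal_stop` (stops before the final codon).
#' @examples
#' translateFrames("ATGAAAGGG", codes = 1)$protein[1]  # "MKG"
#' @export
translateFrames <- function(seq, codes = c(1, 2, 4, 5, 9)) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) < 3L)
    stop("'seq' must be a single DNA string of length >= 3")
  if (!grepl(.iupacRe, seq))
    stop("'seq' contains non-IUPAC characters")
  if (!length(codes)) stop("'codes' must be non-empty")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  tables <- lapply(codes, function(cd)
    Biostrings::getGeneticCode(as.character(cd)))
  translateOne <- function(s, off, tab) {
    s <- substr(s, off, nchar(s))
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  rows <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (fr > 0) seq else rc
    off <- abs(fr)
    for (k in seq_along(codes)) {
      p <- translateOne(s, off, tables[[k]])
      internal <- nchar(p) > 1L &&
        grepl("*", substr(p, 1L, nchar(p) - 1L), fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fr, genetic_code_id = codes[k], protein = p,
        has_internal_stop = internal, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate a sequence as a translatable barcode
#'
#' Passes iff at least one (frame, genetic code) combination yields a
#' translation whose longest internal-stop-free codon run covers at least
#' 90% of the whole codons (amplicons may start mid-codon, so a strict
#' full-length rule would reject valid barcodes). The reported best result
#' is the first passing combination in frame order +1, +2, +3, -1, -2, -3
#' with codes tried in the given order within each frame.
#'
#' @inheritParams translateFrames
#' @param minFraction minimum stop-free fraction of codons (default 0.9).
#' @return list with `pass` (flag) and `best` (one-row data.frame of the
#'   first passing translation, or `NULL`).
#' @examples
#' orfValidate("ATGAAAGGGTTT", codes = 1)$pass
#' @export
orfValidate <- function(seq, codes = c(1, 2, 4, 5, 9), minFraction = 0.9) {
  tr <- translateFrames(seq, codes)
  for (i in seq_len(nrow(tr))) {
    p <- tr$protein[i]
    n <- nchar(p)
    if (n == 0L) next
    runs <- nchar(strsplit(p, "*", fixed = TRUE)[[1]])
    maxRun <- if (length(runs)) max(runs) else 0L
    if (maxRun / n >= minFraction)
      return(list(pass = TRUE, best = tr[i, , drop = FALSE]))
  }
  list(pass = FALSE, best = NULL)
}
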