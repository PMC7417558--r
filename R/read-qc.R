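#' Length/quality filtering of merged reads
#'
#' Discards reads shorter than `minLength` bases or with mean phred quality
#' below `minQuality` (the survey's "< 100 bp or < Q20" rule). A read
#' failing both rules is counted once, as short, so the report partitions
#' the input: `n_in = n_short + n_low_q + n_out`.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param minLength minimum read length in bases (default 100).
#' @param minQuality minimum mean phred quality (default 20).
#' @return list with `kept` (the surviving reads) and `report`
#'   (`n_in`, `n_short`, `n_low_q`, `n_out`).
#' @examples
#' taxa <- genReferenceTaxa(2, markers = "COI", seed = 1)
#' r <- genReads(taxa, 20, fracShort = 0.25, fracLowQ = 0.25, seed = 2)
#' qualityFilter(r)$report
#' @export
qualityFilter <- function(reads, minLength = 100, minQuality = 20) {
  if (minLength < 1) stop("'minLength' must be >= 1")
  if (minQuality < 0 || minQuality > 41)
    stop("'minQuality' must lie in [0, 41]")
  n <- length(reads)
  if (n == 0L)
    return(list(kept = reads,
                report = list(n_in = 0L, n_short = 0L, n_low_q = 0L,
                              n_out = 0L)))
  widths <- Biostrings::width(reads)
  qwidths <- Biostrings::width(Biostrings::quality(reads))
  bad <- which(widths != qwidths)
  if (length(bad)) {
    id <- if (!is.null(names(reads))) names(reads)[bad[1]] else bad[1]
    stop("malformed record: quality and sequence lengths differ for read ",
         id)
  }
  short <- widths < minLength
  lowq <- !short & meanPhred(reads) < minQuality
  keep <- !short & !lowq
  list(kept = reads[keep],
       report = list(n_in = n, n_short = sum(short), n_low_q = sum(lowq),
                     n_out = sum(keep)))
}

#' Pass-through chimera-removal stage
#'
#' Placeholder for the chimera-detection position of the pipeline: removes
#' the ids of a precomputed exclusion list (e.g. produced by an external
#' chimera detector) and nothing else.
#'
#' @param seqs named sequences (character or `DNAStringSet`-like).
#' @param exclude ids to drop.
#' @return `seqs` without the excluded ids.
#' @export
removeChimeras <- function(seqs, exclude = character(0)) {
  if (!length(exclude)) return(seqs)
  seqs[setdiff(names(seqs), exclude)]
}
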