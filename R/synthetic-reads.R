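#' Generate merged reads with planted quality-control failures
#'
#' Simulates single-record merged amplicon reads for the length/quality
#' filter: exactly `round(nReads * fracShort)` reads are shorter than 100 bp,
#' exactly `round(nReads * fracLowQ)` of the remaining reads have mean phred
#' quality below Q20 (at full length), and all others pass both rules.
#' Qualities come from a two-regime model: passing reads draw per-base
#' qualities from 28--41 (mean about Q35), failing reads from 3--19 (mean
#' about Q15), so every read sits unambiguously on one side of the Q20 rule.
#'
#' @param taxa data.frame from [genReferenceTaxa()]; read sequences are
#'   mutated fragments of these references.
#' @param nReads number of reads.
#' @param fracShort,fracLowQ planted failure fractions; their sum must lie in
#'   \[0, 1\].
#' @param seed integer seed.
#' @return A [Biostrings::QualityScaledDNAStringSet] with read ids as names
#'   and the planted category (`"pass"`, `"short"`, `"low_quality"`) in
#'   `mcols(x)$planted`.
#' @examples
#' taxa <- genReferenceTaxa(3, markers = "COI", seed = 1)
#' reads <- genReads(taxa, nReads = 10, fracShort = 0.2, fracLowQ = 0.3,
#'                   seed = 4)
#' table(S4Vectors::mcols(reads)$planted)
#' @export
genReads <- function(taxa, nReads, fracShort = 0, fracLowQ = 0, seed) {
  stopifnotFraction(fracShort, "fracShort")
  stopifnotFraction(fracLowQ, "fracLowQ")
  if (fracShort + fracLowQ > 1 + 1e-12)
    stop("fracShort + fracLowQ must not exceed 1")
  if (nReads < 0) stop("'nReads' must be >= 0")
  nReads <- as.integer(nReads)
  if (nReads == 0L) {
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0)))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(planted = character(0))
    return(out)
  }
  nShort <- round(nReads * fracShort)
  nLowQ <- min(round(nReads * fracLowQ), nReads - nShort)
  withSeed(seed, {
    category <- sample(rep(c("short", "low_quality", "pass"),
                           c(nShort, nLowQ, nReads - nShort - nLowQ)))
    refs <- taxa$sequence
    seqs <- character(nReads)
    quals <- character(nReads)
    for (i in seq_len(nReads)) {
      len <- if (category[i] == "short") sample(30:99, 1) else sample(250:380, 1)
      ref <- refs[sample(length(refs), 1)]
      s <- if (nchar(ref) >= len) {
        st <- sample(nchar(ref) - len + 1L, 1)
        substr(ref, st, st + len - 1L)
      } else paste0(ref, randomDna(len - nchar(ref)))
      # sprinkle ~1% substitutions
      nm <- rbinom(1, len, 0.01)
      if (nm) {
        pos <- sample(len, nm)
        sv <- strsplit(s, "")[[1]]
        sv[pos] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
        s <- paste(sv, collapse = "")
      }
      seqs[i] <- s
      q <- if (category[i] == "low_quality") sample(3:19, len, replace = TRUE)
           else sample(28:41, len, replace = TRUE)
      quals[i] <- rawToChar(as.raw(q + 33L))
    }
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(out) <- sprintf("read_%06d", seq_len(nReads))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(planted = category)
    out
  })
}

#' Write reads to FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  S4Vectors::mcols(reads) <- NULL   # FASTQ carries no per-read metadata
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read FASTQ into a quality-scaled set
#'
#' @param path FASTQ file.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readReadsFastq <- function(path) {
  # the reader attaches then drops an internal metadata column; silence it
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}
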