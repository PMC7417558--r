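#' Bray-Curtis dissimilarity with a dummy pseudo-OTU
#'
#' Computes `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` between all sample
#' pairs after appending one pseudo-OTU of constant value `dummy` (default
#' 0.0001) to every sample, so pairs of all-zero samples are defined (their
#' distance is 0). Counts are used untransformed by default; the
#' square-root of relative abundances is available as an option since both
#' conventions are in circulation for this analysis.
#'
#' @param x an [AbundanceMatrix] or a samples-by-OTU numeric matrix.
#' @param dummy constant pseudo-OTU value appended per sample (default
#'   0.0001; 0 disables it).
#' @param transform `"none"` (raw counts) or `"sqrt_relative"`
#'   (square-root of sample-relative abundances, applied before the dummy).
#' @return A [stats::dist] with sample labels; entries in \[0, 1\].
#' @examples
#' m <- rbind(a = c(1, 0), b = c(0, 1))
#' brayCurtis(m, dummy = 0)  # exactly 1
#' @export
brayCurtis <- function(x, dummy = 1e-4,
                       transform = c("none", "sqrt_relative")) {
  transform <- match.arg(transform)
  m <- if (is(x, "AbundanceMatrix")) abundanceCounts(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (dummy < 0) stop("'dummy' must be >= 0")
  if (transform == "sqrt_relative") {
    tot <- rowSums(m)
    m <- sqrt(m / ifelse(tot == 0, 1, tot))
  }
  if (dummy > 0) m <- cbind(m, dummy_otu = dummy)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(m[i, ] - m[j, ]))
      den <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  stats::as.dist(d)
}
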