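#' Generate a two-group sample-by-OTU abundance matrix
#'
#' Simulates counts for painted vs bare panel communities under a
#' negative-binomial model with per-OTU log-normal baseline means and a
#' per-sample log-normal scale factor. With `locationShift = 0` and
#' `dispersionRatio = 1` the two groups are generated identically, so group
#' labels are exchangeable (the null used for permutation-test calibration).
#'
#' The painted group carries both effects: `locationShift` is a log-fold
#' change applied with alternating sign to successive OTUs (half up, half
#' down, so composition changes, not just scale), and `dispersionRatio`
#' multiplies the standard deviation of the painted samples' log scale
#' factor, spreading those samples out in community space without moving the
#' group's composition.
#'
#' Fixed model constants: baseline means are log-normal(meanlog = log 50,
#' sdlog = 1); counts are negative binomial with size 10; the per-sample log
#' scale factor has baseline sd 0.25.
#'
#' @param nPerGroup samples per group (>= 2).
#' @param nOtus number of OTUs (>= 2).
#' @param locationShift non-negative log-fold-change effect size.
#' @param dispersionRatio positive multiplier of the painted group's
#'   per-sample scale sd.
#' @param seed integer seed.
#' @return An [AbundanceMatrix] with `2 * nPerGroup` samples labelled
#'   `"painted"` then `"bare"`.
#' @examples
#' genAbundance(3, 10, seed = 5)
#' @export
genAbundance <- function(nPerGroup, nOtus, locationShift = 0,
                         dispersionRatio = 1, seed) {
  if (nPerGroup < 2) stop("'nPerGroup' must be >= 2")
  if (nOtus < 2) stop("'nOtus' must be >= 2")
  if (locationShift < 0) stop("'locationShift' must be >= 0")
  if (dispersionRatio <= 0) stop("'dispersionRatio' must be > 0")
  withSeed(seed, {
    n <- 2L * as.integer(nPerGroup)
    group <- rep(c("painted", "bare"), each = nPerGroup)
    m <- exp(rnorm(nOtus, log(50), 1))
    dir <- rep(c(1, -1), length.out = nOtus)
    counts <- matrix(0L, n, nOtus)
    for (i in seq_len(n)) {
      painted <- group[i] == "painted"
      mu <- m * if (painted) exp(locationShift * dir) else 1
      scale <- exp(rnorm(1, 0, 0.25 * if (painted) dispersionRatio else 1))
      counts[i, ] <- rnbinom(nOtus, mu = mu * scale, size = 10)
    }
    dimnames(counts) <- list(sprintf("%s_%02d", group, seq_len(n)),
                             sprintf("OTU_%04d", seq_len(nOtus)))
    AbundanceMatrix(counts, group)
  })
}

#' Write an abundance matrix to CSV
#'
#' Layout: first column `sample_id`, second column `group`, then one column
#' per OTU.
#'
#' @param x an [AbundanceMatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAbundanceCsv <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), group = groupLabels(x),
                   abundanceCounts(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from CSV
#'
#' Expects the layout written by [writeAbundanceCsv()].
#'
#' @param path CSV file.
#' @return An [AbundanceMatrix].
#' @export
readAbundanceCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)[1:2]))
    stop("first two columns must be 'sample_id' and 'group'")
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$sample_id
  AbundanceMatrix(m, df$group)
}
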