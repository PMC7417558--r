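# One-way PERMANOVA on a dissimilarity matrix, written from the
# sums-of-squares identities (no design-matrix projection needed for a
# single factor):
#   SS_total  = (1/N) sum_{i<j} d_ij^2
#   SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
#   pseudo-F  = (SS_between / (a - 1)) / (SS_within / (N - a))

.ssWithin <- function(D2, groupIdx) {
  s <- 0
  for (idx in groupIdx)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  s
}

# Canonical sample order: sort labels, factor groups by order of appearance
# in that sorted order. Makes the permutation stream (hence the p-value)
# invariant to sample reordering and to renaming the groups.
.canonicalize <- function(d, groups) {
  dm <- as.matrix(d)
  labs <- labels(d)
  if (is.null(labs) || !length(labs)) labs <- as.character(seq_len(nrow(dm)))
  dimnames(dm) <- list(labs, labs)
  if (length(groups) != nrow(dm))
    stop("'groups' must have one label per sample")
  ord <- order(labs, method = "radix")
  dm <- dm[ord, ord, drop = FALSE]
  groups <- as.character(groups)[ord]
  g <- factor(groups, levels = unique(groups))
  list(dm = dm, groups = g)
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA of a dissimilarity matrix against a grouping factor.
#' The p-value is `(1 + #{permuted F >= observed F}) / (1 + nPerm)` under
#' random relabelling of the samples with a fixed seed; when the design has
#' two groups and the number of distinct relabellings is at most `nPerm`,
#' all relabellings are enumerated instead and the p-value is the exact
#' fraction with `F >= observed`.
#'
#' @param d a [stats::dist] (e.g. from [brayCurtis()]).
#' @param groups group label per sample, in the sample order of `d`; at
#'   least 2 groups of at least 2 samples each.
#' @param nPerm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return A [PermanovaResult].
#' @examples
#' am <- genAbundance(4, 20, locationShift = 1.5, seed = 1)
#' permanova(brayCurtis(am), groupLabels(am), nPerm = 199, seed = 2)
#' @export
permanova <- function(d, groups, nPerm = 9999, seed = 1) {
  cz <- .canonicalize(d, groups)
  dm <- cz$dm
  g <- cz$groups
  N <- nrow(dm)
  a <- nlevels(g)
  sizes <- table(g)
  if (a < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  D2 <- dm^2
  ssT <- sum(D2[upper.tri(D2)]) / N
  groupIdx <- split(seq_len(N), g)
  ssW <- .ssWithin(D2, groupIdx)
  ssB <- ssT - ssW
  dfB <- a - 1
  dfW <- N - a
  fObs <- (ssB / dfB) / (ssW / dfW)
  fFromLabels <- function(lab) {
    ssw <- .ssWithin(D2, split(seq_len(N), lab))
    ((ssT - ssw) / dfB) / (ssw / dfW)
  }
  exhaustive <- a == 2 && choose(N, sizes[1]) <= nPerm
  if (exhaustive) {
    sets <- utils::combn(N, sizes[1])
    fAll <- apply(sets, 2, function(idx) {
      lab <- rep(levels(g)[2], N)
      lab[idx] <- levels(g)[1]
      fFromLabels(factor(lab, levels = levels(g)))
    })
    p <- mean(fAll >= fObs - 1e-12)
    nUsed <- ncol(sets)
  } else {
    fPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
      fFromLabels(g[sample.int(N)]), numeric(1)))
    p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
    nUsed <- nPerm
  }
  new("PermanovaResult", pseudoF = fObs, R2 = ssB / ssT, pValue = p,
      dfBetween = dfB, dfWithin = dfW, ssBetween = ssB, ssWithin = ssW,
      ssTotal = ssT, nPermutations = nUsed, seed = as.numeric(seed),
      pMethod = if (exhaustive) "exhaustive" else "sampled")
}
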