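# Homogeneity of multivariate dispersions: distances to group centroids in
# the principal-coordinates embedding of a (semimetric) dissimilarity
# matrix, one-way F on those distances, permutation p-value.

#' Test homogeneity of multivariate group dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (double-centred
#' Gower matrix, full eigendecomposition, all non-null axes kept). Because
#' Bray-Curtis is semimetric some eigenvalues are negative; the squared
#' distance of a sample to its group centroid is the squared distance on
#' the positive-eigenvalue axes minus the squared distance on the
#' negative-eigenvalue axes, floored at zero before the square root. The F
#' statistic is the one-way ANOVA F of these centroid distances across
#' groups; its p-value comes from permuting the distances across samples
#' with a fixed seed.
#'
#' @inheritParams permanova
#' @return A [BetadisperResult].
#' @examples
#' am <- genAbundance(5, 20, dispersionRatio = 4, seed = 1)
#' dispersionTest(brayCurtis(am), groupLabels(am), nPerm = 199, seed = 2)
#' @export
dispersionTest <- function(d, groups, nPerm = 999, seed = 1) {
  cz <- .canonicalize(d, groups)
  dm <- cz$dm
  g <- cz$groups
  N <- nrow(dm)
  a <- nlevels(g)
  if (a < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  A <- -0.5 * dm^2
  J <- diag(N) - matrix(1 / N, N, N)
  G <- J %*% A %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(eg$values) > max(abs(eg$values), .Machine$double.eps) * 1e-8
  lambda <- eg$values[keep]
  axes <- sweep(eg$vectors[, keep, drop = FALSE], 2, sqrt(abs(lambda)), "*")
  pos <- lambda > 0
  z <- numeric(N)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    cen <- colMeans(axes[idx, , drop = FALSE])
    dev2 <- sweep(axes[idx, , drop = FALSE], 2, cen)^2
    z[idx] <- sqrt(pmax(0, rowSums(dev2[, pos, drop = FALSE]) -
                           rowSums(dev2[, !pos, drop = FALSE])))
  }
  anovaF <- function(zz) {
    gm <- tapply(zz, g, mean)
    ssb <- sum(table(g) * (gm - mean(zz))^2)
    ssw <- sum((zz - gm[g])^2)
    (ssb / (a - 1)) / (ssw / (N - a))
  }
  fObs <- anovaF(z)
  fPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    anovaF(z[sample.int(N)]), numeric(1)))
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
  new("BetadisperResult", distances = setNames(z, rownames(dm)),
      groups = as.character(g),
      groupMeanDistances = setNames(as.numeric(tapply(z, g, mean)),
                                    levels(g)),
      fStat = fObs, pValue = p, eigenvalues = eg$values,
      nPermutations = nPerm, seed = as.numeric(seed))
}
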