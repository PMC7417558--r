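test_that("alpha diversity matches the stated formulas", {
  a <- alphaDiversity(c(10))
  expect_equal(unlist(a), c(observed = 1, chao1 = 1, shannon = 0,
                            inv_simpson = 1))
  a <- alphaDiversity(c(5, 5))
  expect_equal(a$shannon, log(2))
  expect_equal(a$inv_simpson, 2)
  # S_obs = 5, F1 = 2, F2 = 1 -> chao1 = 5 + 2*1/(2*2) = 5.5
  a <- alphaDiversity(c(1, 1, 2, 3, 4))
  expect_equal(a$observed, 5)
  expect_equal(a$chao1, 5.5)
  expect_error(alphaDiversity(c(0, 0)), "all-zero")
  expect_error(alphaDiversity(c(-1, 2)), "non-negative")
})

test_that("alpha indices agree with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(30, 3)
    if (sum(x) == 0) x[1] <- 1
    a <- alphaDiversity(x)
    expect_equal(a$shannon, vegan::diversity(x), tolerance = 1e-12)
    expect_equal(a$inv_simpson, vegan::diversity(x, "invsimpson"),
                 tolerance = 1e-12)
    expect_equal(a$chao1,
                 unname(vegan::estimateR(matrix(x, 1))["S.chao1", 1]))
  }
})

test_that("alpha-diversity inequality chain holds on random count vectors", {
  set.seed(77)
  for (i in 1:1000) {
    x <- rnbinom(sample(5:60, 1), mu = sample(1:20, 1), size = 1)
    if (sum(x) == 0) x[sample(length(x), 1)] <- 1
    a <- alphaDiversity(x)
    expect_gte(a$chao1, a$observed)
    expect_gte(a$observed + 1e-12, exp(a$shannon))
    expect_gte(exp(a$shannon) + 1e-12, a$inv_simpson)
    expect_gte(a$inv_simpson, 1 - 1e-12)
  }
})

test_that("rarefaction matches the exact hypergeometric expectation", {
  x <- c(12, 7, 3, 1, 1, 0, 25)
  total <- sum(x)
  rc <- rarefactionCurve(x, depths = c(1, total), nIter = 50, seed = 1)
  expect_equal(rc$mean_richness, c(1, sum(x > 0)))
  half <- rarefactionCurve(x, depths = total %/% 2, nIter = 400, seed = 2)
  expect_equal(half$mean_richness, exactRarefaction(x, total %/% 2),
               tolerance = 0.05)
  expect_error(rarefactionCurve(x, depths = total + 1, nIter = 5, seed = 1),
               "exceeds")
})

test_that("Bray-Curtis follows the formula and the dummy convention", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(brayCurtis(m, dummy = 0)), 1)
  m2 <- rbind(a = c(3, 2, 5), b = c(3, 2, 5))
  expect_equal(as.numeric(brayCurtis(m2)), 0)
  # disjoint supports shrink slightly below 1 under the dummy
  d <- as.numeric(brayCurtis(rbind(a = c(1, 0), b = c(0, 1)), dummy = 1e-4))
  expect_equal(d, 2 / (2 + 2e-4))
  # all-zero pair is defined and zero
  z <- as.matrix(brayCurtis(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))))
  expect_equal(z["a", "b"], 0)
  expect_gt(z["a", "c"], 0.99)
})

test_that("Bray-Curtis agrees with vegan and stays in [0, 1]", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rnbinom(6 * 12, mu = 8, size = 2), 6, 12)
    rownames(m) <- paste0("s", 1:6)
    d <- brayCurtis(m)
    ref <- vegan::vegdist(cbind(m, 1e-4), method = "bray")
    expect_equal(as.numeric(d), as.numeric(ref), tolerance = 1e-12)
    dm <- as.matrix(d)
    expect_true(all(dm >= 0 & dm <= 1))
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 6))
  }
  # the sqrt-relative transform variant is a valid dissimilarity too
  m <- matrix(rnbinom(8 * 10, mu = 20, size = 2), 8, 10,
              dimnames = list(paste0("s", 1:8), NULL))
  ds <- brayCurtis(m, transform = "sqrt_relative")
  tot <- rowSums(m)
  ref <- vegan::vegdist(cbind(sqrt(m / tot), 1e-4), method = "bray")
  expect_equal(as.numeric(ds), as.numeric(ref), tolerance = 1e-12)
})

test_that("PERMANOVA partitions sums of squares and matches adonis2", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:5) {
    am <- genAbundance(4, 15, locationShift = runif(1), seed = 100 + i)
    d <- brayCurtis(am)
    g <- groupLabels(am)
    pv <- permanova(d, g, nPerm = 99, seed = 1)
    expect_lt(abs(pv@ssBetween + pv@ssWithin - pv@ssTotal), 1e-9)
    ad <- vegan::adonis2(d ~ g, permutations = 99)
    expect_equal(pv@pseudoF, ad$F[1], tolerance = 1e-10)
    expect_equal(pv@R2, ad$R2[1], tolerance = 1e-10)
    expect_equal(pv@ssBetween, ad$SumOfSqs[1], tolerance = 1e-10)
    expect_equal(pv@ssWithin, ad$SumOfSqs[2], tolerance = 1e-10)
  }
})

test_that("equal pairwise distances give a structureless PERMANOVA", {
  n <- 8
  dm <- matrix(0.5, n, n); diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:n)
  g <- rep(c("A", "B"), each = 4)
  pv <- permanova(stats::as.dist(dm), g, nPerm = 99, seed = 1)
  expect_equal(pv@pValue, 1)
})

test_that("small two-group designs are enumerated exhaustively", {
  # 6 samples, within-group distance 0.1, between-group 0.9
  g <- rep(c("A", "B"), each = 3)
  dm <- matrix(0.9, 6, 6)
  for (i in 1:6) for (j in 1:6)
    if (g[i] == g[j]) dm[i, j] <- 0.1
  diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  pv <- permanova(stats::as.dist(dm), g, nPerm = 9999, seed = 1)
  expect_equal(pv@pMethod, "exhaustive")
  expect_equal(pv@nPermutations, choose(6, 3))
  # brute force over all 20 relabellings
  sets <- combn(6, 3)
  fAll <- apply(sets, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"
    oraclePermanovaF(dm, lab)
  })
  expect_equal(pv@pseudoF, oraclePermanovaF(dm, g), tolerance = 1e-12)
  expect_equal(pv@pValue, mean(fAll >= pv@pseudoF - 1e-12))
  expect_equal(pv@pValue, 2 / 20)
})

test_that("PERMANOVA p-values ignore sample order and group names", {
  am <- genAbundance(4, 12, locationShift = 0.5, seed = 42)
  d <- brayCurtis(am)
  g <- groupLabels(am)
  p0 <- pValue(permanova(d, g, nPerm = 199, seed = 7))
  # reorder samples
  perm <- sample(length(g))
  dm <- as.matrix(d)[perm, perm]
  p1 <- pValue(permanova(stats::as.dist(dm), g[perm], nPerm = 199, seed = 7))
  expect_equal(p1, p0)
  # rename groups
  g2 <- ifelse(g == "painted", "Zpaint", "Abare")
  p2 <- pValue(permanova(d, g2, nPerm = 199, seed = 7))
  expect_equal(p2, p0)
  expect_error(permanova(d, rep("A", length(g)), nPerm = 99, seed = 1),
               "2 groups")
  expect_error(permanova(d, c("A", rep("B", length(g) - 1)), nPerm = 99,
                         seed = 1), "at least 2 samples")
})

test_that("dispersion distances match a hand-worked Euclidean example", {
  pts <- rbind(a = c(0, 0), b = c(2, 0), c = c(4, 0), d = c(8, 0))
  d <- stats::dist(pts)
  g <- c("A", "A", "B", "B")
  bd <- dispersionTest(d, g, nPerm = 99, seed = 1)
  expect_equal(unname(bd@distances[c("a", "b", "c", "d")]), c(1, 1, 2, 2),
               tolerance = 1e-10)
  expect_equal(unname(bd@groupMeanDistances), c(1, 2), tolerance = 1e-10)
})

test_that("dispersion test agrees with vegan betadisper centroids", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:5) {
    am <- genAbundance(5, 15, dispersionRatio = runif(1, 1, 3),
                       seed = 200 + i)
    d <- brayCurtis(am)
    g <- groupLabels(am)
    bd <- dispersionTest(d, g, nPerm = 99, seed = 1)
    vb <- vegan::betadisper(d, g, type = "centroid")
    expect_equal(sort(unname(bd@distances)), sort(unname(vb$distances)),
                 tolerance = 1e-8)
    expect_equal(bd@fStat, anova(vb)$`F value`[1], tolerance = 1e-8)
  }
})

test_that("rank aggregation produces relative abundances per sample", {
  taxa <- genReferenceTaxa(10, markers = "COI", seed = 1)
  ht <- genHitTable(sprintf("OTU_%04d", 1:10), taxa, c(clean = 1), seed = 2)
  pm <- split(ht$hits, factor(ht$hits$qseqid, unique(ht$hits$qseqid)))
  asg <- adjudicateAll(ht$truth$query_id, pm, lineage = lineageMap(taxa))
  am <- genAbundance(2, 10, seed = 3)
  rel <- aggregateRank(am, asg, "phylum")
  expect_equal(unname(rowSums(rel)), rep(1, 4), tolerance = 1e-9)
  expect_error(aggregateRank(am, asg, "clade"), "rank")
  # two phyla with 30/70 counts -> 0.3/0.7
  asg2 <- asg
  asg2$phylum <- rep(c("P1", "P2"), each = 5)
  cts <- matrix(0L, 2, 10,
                dimnames = list(c("s1", "s2"), sprintf("OTU_%04d", 1:10)))
  cts[1, ] <- c(rep(6L, 5), rep(14L, 5))
  cts[2, ] <- c(rep(3L, 5), rep(7L, 5))
  am2 <- AbundanceMatrix(cts, c("painted", "bare"))
  rel2 <- aggregateRank(am2, asg2, "phylum")
  expect_equal(unname(rel2[, "P1"]), c(0.3, 0.3))
  expect_equal(unname(rel2[, "P2"]), c(0.7, 0.7))
  # all-zero sample stays zero and is flagged
  cts[2, ] <- 0L
  am3 <- AbundanceMatrix(cts, c("painted", "bare"))
  rel3 <- aggregateRank(am3, asg2, "phylum")
  expect_equal(unname(rowSums(rel3)), c(1, 0))
  expect_equal(unname(attr(rel3, "all_zero")), c(FALSE, TRUE))
  # unassigned OTUs pool into "Unassigned"
  asg3 <- asg2
  asg3$phylum[1] <- NA
  expect_true("Unassigned" %in% colnames(aggregateRank(am2, asg3, "phylum")))
})

test_that("marker-exclusive taxa match brute-force set algebra", {
  same <- list(a = c("X", "Y"), b = c("X", "Y"))
  ex <- markerExclusiveTaxa(same)$exclusive
  expect_true(all(lengths(ex) == 0))
  one <- markerExclusiveTaxa(list(coi = c("P1", "P2")))
  expect_equal(one$exclusive$coi, c("P1", "P2"))
  set.seed(6)
  pool <- paste0("Phy", 1:15)
  sets <- lapply(1:4, function(i) sample(pool, sample(3:10, 1)))
  names(sets) <- c("16S", "18S", "23S", "COI")
  out <- markerExclusiveTaxa(sets)
  for (i in seq_along(sets)) {
    brute <- sets[[i]][!sets[[i]] %in% unique(unlist(sets[-i]))]
    expect_setequal(out$exclusive[[i]], brute)
  }
  # exclusive sets are pairwise disjoint
  allEx <- unlist(out$exclusive)
  expect_equal(anyDuplicated(allEx), 0)
  expect_equal(sum(out$shared$n_markers == 1 &
                     out$shared$taxon %in% allEx), length(allEx))
})
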