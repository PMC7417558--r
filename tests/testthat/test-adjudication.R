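hitRow <- function(qseqid = "q1", sseqid = "S1", length = 250, pident = 99,
                   gaps = 0, sstart = 1, send = 250, qcovs = 100,
                   evalue = 1e-50, bitscore = 400, staxids = "1",
                   stitle = "Alphagenus epithetus isolate A1 gene") {
  data.frame(qseqid = qseqid, sseqid = sseqid, length = length,
             pident = pident, gaps = gaps, sstart = sstart, send = send,
             qcovs = qcovs, evalue = evalue, bitscore = bitscore,
             staxids = staxids, stitle = stitle, stringsAsFactors = FALSE)
}

test_that("hit-table parsing handles both dialects and reports bad lines", {
  l12 <- paste("OTU_1", "ACC1.1", 300, 99.1, 0, 1, 300, 100, 1e-50, 550,
               "123", "Fictoceras simulans COI", sep = "\t")
  p <- parseHitTable(l12, "primary")
  expect_length(p, 1)
  expect_equal(p[["OTU_1"]]$stitle, "Fictoceras simulans COI")
  expect_equal(p[["OTU_1"]]$pident, 99.1)

  l10 <- paste("OTU_1", "Fictoceras_simulans|B1", 300, 99.1, 0, 1, 300, 100,
               1e-50, 550, sep = "\t")
  expect_error(parseHitTable(l10, "primary"), "line 1")
  f <- parseHitTable(l10, "fallback")
  expect_equal(f[["OTU_1"]]$stitle, "")
  expect_equal(f[["OTU_1"]]$sseqid, "Fictoceras_simulans|B1")

  bad <- paste("OTU_1", "ACC1.1", "xxx", 99.1, 0, 1, 300, 100, 1e-50, 550,
               "123", "t", sep = "\t")
  expect_error(parseHitTable(bad, "primary"), "numeric field at line 1")

  # 5 rows over 2 queries: map keys and per-query order preserved
  rows <- c(
    paste("q2", "S1", 210, 95, 0, 1, 210, 100, 1e-30, 300, "1", "A b x",
          sep = "\t"),
    paste("q1", "S2", 220, 96, 0, 1, 220, 100, 1e-31, 301, "1", "A b x",
          sep = "\t"),
    paste("q2", "S3", 230, 97, 0, 1, 230, 100, 1e-32, 302, "1", "A b x",
          sep = "\t"),
    paste("q1", "S4", 240, 98, 0, 1, 240, 100, 1e-33, 303, "1", "A b x",
          sep = "\t"),
    paste("q2", "S5", 250, 99, 0, 1, 250, 100, 1e-34, 304, "1", "A b x",
          sep = "\t"))
  m <- parseHitTable(paste(rows, collapse = "\n"), "primary")
  expect_equal(names(m), c("q2", "q1"))
  expect_equal(m[["q2"]]$sseqid, c("S1", "S3", "S5"))
  expect_equal(m[["q1"]]$sseqid, c("S2", "S4"))
})

test_that("hit tables written to disk parse back identically", {
  taxa <- genReferenceTaxa(8, markers = "COI", seed = 1)
  ht <- genHitTable(paste0("q", 1:12), taxa,
                    c(clean = 0.5, low_confidence = 0.5), seed = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeHitTable(ht$hits, tmp, "primary")
  back <- parseHitTable(tmp, "primary")
  expect_equal(do.call(rbind, unname(back))$sseqid, ht$hits$sseqid)
  expect_equal(do.call(rbind, unname(back))$pident, ht$hits$pident)
})

test_that("confidence filtering applies thresholds with boundary semantics", {
  t <- filterThresholds()
  # boundary values pass
  ok <- hitRow(length = 200, pident = 90, qcovs = 100, gaps = 0)
  expect_equal(nrow(filterHits(ok, t)$surviving), 1)
  # identity just below threshold fails with reason 'identity'
  low <- hitRow(length = 250, pident = 89.9)
  f <- filterHits(low, t)
  expect_equal(nrow(f$surviving), 0)
  expect_equal(f$removals$reason, "identity")
  # banned keyword, case-insensitive whole word
  ban <- hitRow(pident = 99, stitle = "Uncultured bacterium clone A")
  expect_equal(filterHits(ban, t)$removals$reason, "banned_keyword")
  sub <- hitRow(stitle = "Unculturedium genus species")  # not a whole word
  expect_equal(nrow(filterHits(sub, t)$surviving), 1)
  # first violated rule in stated order wins
  multi <- hitRow(length = 100, pident = 50, qcovs = 80, gaps = 3)
  expect_equal(filterHits(multi, t)$removals$reason, "alignment_length")
})

test_that("relaxing any single threshold never decreases survivors", {
  set.seed(5)
  hits <- do.call(rbind, lapply(1:40, function(i)
    randomHitFrame("q", 1)))
  base <- filterThresholds()
  nBase <- nrow(filterHits(hits, base)$surviving)
  relaxed <- list(
    filterThresholds(minAlignmentLength = 150),
    filterThresholds(minPident = 80),
    filterThresholds(requiredQcovs = 90),
    filterThresholds(maxGaps = 2),
    filterThresholds(bannedTitleKeywords = "zzznonword"))
  for (t in relaxed)
    expect_gte(nrow(filterHits(hits, t)$surviving), nBase)
})

test_that("hit ranking follows the four criteria then subject id", {
  h <- rbind(hitRow(sseqid = "A", pident = 98),
             hitRow(sseqid = "B", pident = 99))
  expect_equal(rankHits(h)$sseqid, c("B", "A"))
  h <- rbind(hitRow(sseqid = "A", evalue = 1e-40),
             hitRow(sseqid = "B", evalue = 1e-50))
  expect_equal(rankHits(h)$sseqid, c("B", "A"))
  h <- rbind(hitRow(sseqid = "A", qcovs = 99), hitRow(sseqid = "B"))
  expect_equal(rankHits(h)$sseqid, c("B", "A"))
  h <- rbind(hitRow(sseqid = "A", gaps = 1), hitRow(sseqid = "B"))
  expect_equal(rankHits(h)$sseqid, c("B", "A"))
  h <- rbind(hitRow(sseqid = "AB2"), hitRow(sseqid = "AB1"))
  expect_equal(rankHits(h)$sseqid, c("AB1", "AB2"))
  # stable under permutation
  set.seed(3)
  h <- do.call(rbind, lapply(1:8, function(i) randomHitFrame("q", 1)))
  r1 <- rankHits(h)
  r2 <- rankHits(h[sample(nrow(h)), ])
  expect_equal(r1$sseqid, r2$sseqid)
})

test_that("assignment cascade covers every branch", {
  # both lists empty
  a <- assignTaxonomy("o1")
  expect_equal(a$status, "unassigned_no_hit")
  expect_equal(nrow(a$evidence[[1]]), 0)
  # fallback used when primary empty
  fb <- hitRow(sseqid = "Betagenus_brevis|X9")
  attr(fb, "dialect") <- "fallback"
  a <- assignTaxonomy("o2", NULL, fb)
  expect_equal(a$status, "assigned_top_hit")
  expect_equal(a$source_db, "fallback")
  expect_equal(a$genus, "Betagenus")
  expect_equal(a$species, "Betagenus brevis")
  # two genera with a strict pident winner -> tiebreak
  two <- rbind(hitRow(sseqid = "S1", pident = 99,
                      stitle = "Alphagenus primus gene"),
               hitRow(sseqid = "S2", pident = 97,
                      stitle = "Betagenus brevis gene"))
  a <- assignTaxonomy("o3", two)
  expect_equal(a$status, "assigned_tiebreak")
  expect_equal(a$genus, "Alphagenus")
  # two genera tied on all four criteria -> dubious
  tie <- rbind(hitRow(sseqid = "S1", stitle = "Alphagenus primus gene"),
               hitRow(sseqid = "S2", stitle = "Betagenus brevis gene"))
  a <- assignTaxonomy("o4", tie)
  expect_equal(a$status, "dubious")
  expect_true(is.na(a$genus))
  # all hits banned -> removed_banned
  ban <- rbind(hitRow(sseqid = "S1", stitle = "Uncultured clone 1"),
               hitRow(sseqid = "S2", stitle = "environmental sample 2"))
  expect_equal(assignTaxonomy("o5", ban)$status, "removed_banned")
  # all filtered for mixed reasons -> unassigned_all_filtered
  filt <- rbind(hitRow(sseqid = "S1", pident = 70),
                hitRow(sseqid = "S2", stitle = "Uncultured clone 1"))
  expect_equal(assignTaxonomy("o6", filt)$status, "unassigned_all_filtered")
  # more than 5 hits: warning, extras ignored
  many <- do.call(rbind, lapply(1:7, function(i)
    hitRow(sseqid = paste0("S", i), pident = 99 - i * 0.5)))
  expect_warning(a <- assignTaxonomy("o7", many), "first 5")
  expect_equal(nrow(a$evidence[[1]]), 5)
})

test_that("lineage map fills higher ranks of assignments", {
  taxa <- genReferenceTaxa(6, markers = "COI", seed = 1)
  ht <- genHitTable(paste0("q", 1:6), taxa, c(clean = 1), seed = 2)
  pm <- split(ht$hits, factor(ht$hits$qseqid, unique(ht$hits$qseqid)))
  asg <- adjudicateAll(ht$truth$query_id, pm, lineage = lineageMap(taxa))
  expect_equal(asg$genus, ht$truth$true_genus)
  lm <- lineageMap(taxa)
  expect_equal(asg$phylum, lm$phylum[match(asg$genus, lm$genus)])
})

test_that("adjudication agrees with the brute-force oracle on 500 random tables", {
  set.seed(99)
  nAgree <- 0
  for (i in 1:500) {
    nP <- sample(0:5, 1)
    nF <- if (nP == 0) sample(0:5, 1) else sample(0:3, 1)
    prim <- randomHitFrame("q", nP)
    fall <- randomHitFrame("q", nF)
    if (!is.null(fall)) attr(fall, "dialect") <- "fallback"
    got <- assignTaxonomy("q", prim, fall)
    want <- oracleAdjudicate(prim, fall)
    expect_equal(got$status, want$status, info = paste("case", i))
    if (grepl("^assigned", want$status)) {
      expect_equal(got$genus, want$genus, info = paste("case", i))
      expect_equal(got$best_sseqid, want$winner, info = paste("case", i))
    }
    nAgree <- nAgree + 1
  }
  expect_equal(nAgree, 500)
})

test_that("assignments are invariant to hit-row shuffling", {
  set.seed(17)
  for (i in 1:25) {
    h <- randomHitFrame("q", sample(2:5, 1))
    a1 <- assignTaxonomy("q", h)
    a2 <- assignTaxonomy("q", h[sample(nrow(h)), ])
    expect_equal(a1$status, a2$status)
    expect_equal(a1$best_sseqid, a2$best_sseqid)
    expect_equal(a1$genus, a2$genus)
  }
})

test_that("planted cases map one-to-one onto adjudication statuses", {
  taxa <- genReferenceTaxa(24, markers = "COI", seed = 1)
  cl <- genChecklist(taxa, 0.25, seed = 2)
  fr <- c(clean = 0.25, no_hit = 0.15, low_confidence = 0.2,
          ambiguous = 0.2, banned_keyword = 0.1, nis = 0.1)
  ht <- genHitTable(sprintf("OTU_%03d", 1:80), taxa, fr, checklist = cl,
                    seed = 3)
  pm <- split(ht$hits, factor(ht$hits$qseqid, unique(ht$hits$qseqid)))
  asg <- adjudicateAll(ht$truth$query_id, pm)
  expected <- c(clean = "assigned_top_hit", no_hit = "unassigned_no_hit",
                low_confidence = "unassigned_all_filtered",
                ambiguous = "assigned_tiebreak",
                banned_keyword = "removed_banned", nis = "assigned_top_hit")
  expect_equal(asg$status,
               unname(expected[ht$truth$planted_case]))
  assigned <- grepl("^assigned", asg$status)
  expect_equal(asg$genus[assigned], ht$truth$true_genus[assigned])
  expect_equal(asg$species[assigned], ht$truth$true_species[assigned])
})

test_that("assignment summaries partition the OTUs", {
  taxa <- genReferenceTaxa(10, markers = "COI", seed = 1)
  ht <- genHitTable(paste0("q", 1:20), taxa,
                    c(clean = 0.5, no_hit = 0.25, low_confidence = 0.25),
                    seed = 4)
  pm <- split(ht$hits, factor(ht$hits$qseqid, unique(ht$hits$qseqid)))
  asg <- adjudicateAll(ht$truth$query_id, pm)
  s <- summarizeAssignments(asg)
  expect_equal(sum(unlist(s$status)), 20)
  expect_equal(sum(unlist(s$deepest_rank)), 20)
  expect_lte(s$n_species, s$n_genus)
  expect_equal(s$status$assigned_top_hit, 10)
  expect_equal(s$status$unassigned_no_hit, 5)
  empty <- summarizeAssignments(adjudicateAll(character(0)))
  expect_equal(sum(unlist(empty$status)), 0)
})
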