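# Independent oracles, each written directly from the stated rules and kept
# free of the package's own code paths.

# --- global-alignment identity oracle (plain R dynamic programming) -------
# match +1, mismatch -1, linear gap -2; cell ties prefer the diagonal move
# (ties fall toward matches), then the up move.
oracleIdentity <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  Tb <- matrix(0L, n + 1, m + 1)
  H[, 1] <- -2 * (0:n); Tb[, 1] <- 1L
  H[1, ] <- -2 * (0:m); Tb[1, ] <- 2L
  Tb[1, 1] <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      d <- H[i - 1, j - 1] + if (av[i - 1] == bv[j - 1]) 1 else -1
      u <- H[i - 1, j] - 2
      l <- H[i, j - 1] - 2
      best <- d; mv <- 0L
      if (u > best) { best <- u; mv <- 1L }
      if (l > best) { best <- l; mv <- 2L }
      H[i, j] <- best; Tb[i, j] <- mv
    }
  }
  i <- n + 1; j <- m + 1; matches <- 0L; columns <- 0L
  while (i > 1 || j > 1) {
    mv <- if (i == 1) 2L else if (j == 1) 1L else Tb[i, j]
    columns <- columns + 1L
    if (mv == 0L) {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (mv == 1L) i <- i - 1 else j <- j - 1
  }
  list(matches = matches, columns = columns, identity = matches / columns,
       score = H[n + 1, m + 1])
}

# alignment-identity oracle for long sequences: an independent aligner
# (Biostrings) under the same scoring scheme
alignerIdentity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

# --- adjudication oracle ---------------------------------------------------
# Brute-force re-statement of the cascade: predicate filter, exhaustive
# pairwise comparisons for the ranking, explicit status rules.
oracleHitPasses <- function(h, minLen = 200, minPid = 90, reqCov = 100,
                            maxGaps = 0,
                            banned = c("uncultured", "unidentified",
                                       "unclassified", "environmental")) {
  words <- tolower(unlist(strsplit(h$stitle, "[^A-Za-z]+")))
  h$length >= minLen && h$pident >= minPid && h$qcovs >= reqCov &&
    h$gaps <= maxGaps && !any(words %in% banned)
}

# TRUE when hit i precedes hit j in the ranked order
oracleBefore <- function(hi, hj) {
  if (hi$pident != hj$pident) return(hi$pident > hj$pident)
  if (hi$evalue != hj$evalue) return(hi$evalue < hj$evalue)
  if (hi$qcovs != hj$qcovs) return(hi$qcovs > hj$qcovs)
  if (hi$gaps != hj$gaps) return(hi$gaps < hj$gaps)
  hi$sseqid < hj$sseqid
}

oracleGenusOf <- function(h, dialect) {
  toks <- if (dialect == "primary")
    unlist(strsplit(h$stitle, "[^A-Za-z]+"))
  else {
    tt <- unlist(strsplit(h$sseqid, "[|_]"))
    tt[grepl("^[A-Za-z]+$", tt)]
  }
  toks <- toks[nzchar(toks)]
  if (length(toks) < 1) NA_character_ else toks[1]
}

oracleAdjudicate <- function(primary, fallback) {
  if ((is.null(primary) || !nrow(primary)) &&
      (is.null(fallback) || !nrow(fallback)))
    return(list(status = "unassigned_no_hit", genus = NA_character_,
                winner = NA_character_))
  if (!is.null(primary) && nrow(primary)) {
    hits <- primary; dialect <- "primary"
  } else {
    hits <- fallback; dialect <- "fallback"
  }
  if (nrow(hits) > 5) hits <- hits[1:5, , drop = FALSE]
  pass <- vapply(seq_len(nrow(hits)), function(i)
    oracleHitPasses(hits[i, ]), logical(1))
  surv <- hits[pass, , drop = FALSE]
  if (!nrow(surv)) {
    allBanned <- all(vapply(seq_len(nrow(hits)), function(i) {
      h <- hits[i, ]
      words <- tolower(unlist(strsplit(h$stitle, "[^A-Za-z]+")))
      # banned is the reason only when every numeric rule passed
      h$length >= 200 && h$pident >= 90 && h$qcovs >= 100 && h$gaps <= 0 &&
        any(words %in% c("uncultured", "unidentified", "unclassified",
                         "environmental"))
    }, logical(1)))
    return(list(status = if (allBanned) "removed_banned"
                         else "unassigned_all_filtered",
                genus = NA_character_, winner = NA_character_))
  }
  # winner: the hit that precedes all others under exhaustive comparison
  k <- nrow(surv)
  winnerIdx <- which(vapply(seq_len(k), function(i)
    all(vapply(seq_len(k)[-i], function(j)
      oracleBefore(surv[i, ], surv[j, ]), logical(1))) || k == 1,
    logical(1)))[1]
  genera <- vapply(seq_len(k), function(i) oracleGenusOf(surv[i, ], dialect),
                   character(1))
  win <- surv[winnerIdx, ]
  winGenus <- genera[winnerIdx]
  if (length(unique(genera)) == 1)
    return(list(status = "assigned_top_hit", genus = winGenus,
                winner = win$sseqid))
  othersIdx <- which(genera != winGenus)
  strict <- vapply(othersIdx, function(j) {
    hj <- surv[j, ]
    !(win$pident == hj$pident && win$evalue == hj$evalue &&
        win$qcovs == hj$qcovs && win$gaps == hj$gaps)
  }, logical(1))
  if (all(strict))
    list(status = "assigned_tiebreak", genus = winGenus, winner = win$sseqid)
  else
    list(status = "dubious", genus = NA_character_, winner = NA_character_)
}

# random hit frame exercising values around every threshold boundary
randomHitFrame <- function(qid, nHits) {
  if (nHits == 0) return(NULL)
  genera <- c("Alphagenus", "Betagenus", "Gammagenus")
  sseqids <- sprintf("SUB%03d", sample(999, nHits))
  rows <- lapply(seq_len(nHits), function(i) {
    g <- sample(genera, 1)
    title <- if (runif(1) < 0.2)
      paste(sample(c("Uncultured", "unidentified", "Unclassified",
                     "environmental"), 1), "organism clone X1")
    else paste(g, "epithetus isolate", i, "marker gene")
    data.frame(qseqid = qid,
               sseqid = sseqids[i],
               length = sample(c(150, 199, 200, 201, 350), 1),
               pident = sample(c(85, 89.9, 90, 95.5, 99), 1),
               gaps = sample(0:2, 1, prob = c(.6, .2, .2)),
               sstart = 1, send = 300,
               qcovs = sample(c(100, 100, 99, 95), 1),
               evalue = sample(c(1e-60, 1e-40, 1e-20), 1),
               bitscore = round(runif(1, 100, 600), 1),
               staxids = "1", stitle = title,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- exact rarefaction expectation ----------------------------------------
exactRarefaction <- function(x, n) {
  x <- x[x > 0]
  N <- sum(x)
  sum(1 - exp(lchoose(N - x, n) - lchoose(N, n)))
}

# --- Otsu oracle: exhaustive threshold search ------------------------------
oracleOtsu <- function(img) {
  v <- as.vector(img)
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best + 1e-12) { best <- bc; bestT <- t }
  }
  bestT
}

# --- PERMANOVA brute force -------------------------------------------------
oraclePermanovaF <- function(dm, groups) {
  N <- nrow(dm)
  lev <- unique(groups)
  a <- length(lev)
  ssT <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssT <- ssT + dm[i, j]^2
  ssT <- ssT / N
  ssW <- 0
  for (g in lev) {
    idx <- which(groups == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + dm[i, j]^2
    ssW <- ssW + s / length(idx)
  }
  ((ssT - ssW) / (a - 1)) / (ssW / (N - a))
}

# --- misc builders ---------------------------------------------------------
makeReads <- function(seqs, quals) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(vapply(quals, function(q)
      rawToChar(as.raw(q + 33L)), character(1))))
  names(x) <- sprintf("r%03d", seq_along(seqs))
  x
}

mutateSeq <- function(s, nSub) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), nSub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# deterministic pseudo-random fraction in [0.2, 0.8] for panel tests
runifSeeded <- function(i) 0.2 + 0.6 * ((i * 37) %% 50) / 50

# overwrite three stretches of the sequence with a stop block that plants
# TAA in every forward residue class and TTA (= TAA on the reverse strand)
# in every reverse residue class, so no frame under any common genetic code
# can be >= 90% stop-free
makePseudogene <- function(s) {
  block <- strsplit("TAAGGGGTAAGGGGTAAGGGGTTAGGGGTTAGGGGTTA", "")[[1]]
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  for (a0 in pmax(1L, round(L * c(0.15, 0.45, 0.75)))) {
    p <- min(a0, L - length(block))
    v[p:(p + length(block) - 1L)] <- block
  }
  paste(v, collapse = "")
}
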