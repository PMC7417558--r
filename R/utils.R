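# Internal helpers shared across modules.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators route their randomness
# through this so no call touches global random state.
withSeed <- function(seed, code) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split n items into integer counts proportional to `fracs` (which must sum
# to 1 within tol), using floors plus largest remainders; deterministic and
# always sums to n. Ties in remainders fall to the earlier element.
apportion <- function(n, fracs, tol = 1e-9) {
  if (abs(sum(fracs) - 1) > tol)
    stop("case fractions must sum to 1")
  raw <- n * fracs
  base <- floor(raw + tol)
  left <- n - sum(base)
  if (left > 0) {
    rem <- raw - base
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Mean phred quality of each read in a QualityScaledDNAStringSet.
meanPhred <- function(reads) {
  q <- methods::as(Biostrings::quality(reads), "IntegerList")
  vapply(q, function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
}

phredToString <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnotFraction <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", what, "' must be a single value in [0, 1]")
}
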