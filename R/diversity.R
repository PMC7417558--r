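# Alpha diversity, rarefaction and rank aggregation.

#' Alpha-diversity indices of one sample
#'
#' Computes the four survey indices from a vector of OTU counts:
#' observed richness `S_obs`; bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts (well defined even when `F2 = 0`); Shannon entropy
#' `-sum p_i ln p_i` (natural log); and inverse Simpson `1 / sum p_i^2`.
#'
#' @param counts non-negative numeric vector of OTU counts, not all zero.
#' @return list with `observed`, `chao1`, `shannon`, `inv_simpson`.
#' @examples
#' alphaDiversity(c(5, 5))  # shannon = log(2), inv_simpson = 2
#' @export
alphaDiversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero sample has no diversity")
  x <- counts[counts > 0]
  sObs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  p <- x / total
  list(observed = sObs,
       chao1 = sObs + f1 * (f1 - 1) / (2 * (f2 + 1)),
       shannon = -sum(p * log(p)),
       inv_simpson = 1 / sum(p^2))
}

#' Rarefaction curve by repeated subsampling
#'
#' Mean observed richness when the sample is subsampled without replacement
#' to each requested depth, averaged over `nIter` draws. At the full depth
#' the curve equals the observed richness exactly.
#'
#' @param counts non-negative integer OTU counts for one sample.
#' @param depths subsampling depths, each `<=` the sample total.
#' @param nIter number of random subsamples per depth (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean_richness`.
#' @export
rarefactionCurve <- function(counts, depths, nIter = 100, seed) {
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds the sample total")
  if (any(depths < 0)) stop("depths must be non-negative")
  pool <- rep.int(seq_along(counts), counts)
  withSeed(seed, {
    mr <- vapply(depths, function(d) {
      if (d == 0) return(0)
      if (d == total) return(sum(counts > 0))
      mean(vapply(seq_len(nIter), function(i)
        length(unique(sample(pool, d))), numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, mean_richness = mr)
  })
}

#' Aggregate an abundance matrix to relative abundances at a rank
#'
#' Sums OTU counts per taxon at the requested rank (OTUs without an
#' assignment at that rank are pooled into `"Unassigned"`) and converts each
#' sample row to relative abundances. All-zero samples stay all-zero and are
#' flagged in the `all_zero` attribute.
#'
#' @param x an [AbundanceMatrix].
#' @param assignments data.frame from [adjudicateAll()] covering the OTUs of
#'   `x`.
#' @param rank one of `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return matrix of relative abundances, samples in rows, taxa in columns;
#'   attribute `all_zero` marks empty samples.
#' @export
aggregateRank <- function(x, assignments, rank = "phylum") {
  ranks <- c(.rankCols, "genus", "species")
  if (!rank %in% ranks)
    stop("'rank' must be one of: ", paste(ranks, collapse = ", "))
  cts <- abundanceCounts(x)
  idx <- match(colnames(cts), assignments$otu_id)
  if (anyNA(idx))
    stop("every OTU in the matrix needs an assignment row")
  taxon <- assignments[[rank]][idx]
  taxon[is.na(taxon)] <- "Unassigned"
  agg <- t(rowsum(t(cts), group = taxon))
  totals <- rowSums(agg)
  rel <- agg / ifelse(totals == 0, 1, totals)
  attr(rel, "all_zero") <- totals == 0
  rel
}

#' Exclusive and shared taxa across markers
#'
#' For each marker, the taxa seen by it and no other marker, plus a
#' breakdown of how many markers share each taxon (the Venn-diagram
#' numbers).
#'
#' @param taxonSets named list of character vectors, one per marker.
#' @return list with `exclusive` (named list of exclusive sets, pairwise
#'   disjoint) and `shared` (data.frame `taxon`, `n_markers`, `markers`).
#' @export
markerExclusiveTaxa <- function(taxonSets) {
  if (!length(taxonSets)) stop("need at least one marker set")
  taxonSets <- lapply(taxonSets, unique)
  exclusive <- lapply(seq_along(taxonSets), function(i)
    setdiff(taxonSets[[i]], unlist(taxonSets[-i], use.names = FALSE)))
  names(exclusive) <- names(taxonSets)
  allTaxa <- sort(unique(unlist(taxonSets, use.names = FALSE)))
  inSet <- vapply(taxonSets, function(s) allTaxa %in% s,
                  logical(length(allTaxa)))
  inSet <- matrix(inSet, nrow = length(allTaxa),
                  dimnames = list(allTaxa, names(taxonSets)))
  shared <- data.frame(
    taxon = allTaxa,
    n_markers = rowSums(inSet),
    markers = apply(inSet, 1, function(v)
      paste(colnames(inSet)[v], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  list(exclusive = exclusive, shared = shared)
}
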