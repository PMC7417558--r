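#' Pairwise global-alignment identity
#'
#' Percent identity between two DNA sequences under a global
#' Needleman-Wunsch alignment with match +1, mismatch -1 and linear gap
#' penalty -2; alignment-score ties are broken toward matches. Identity is
#' the number of matching columns divided by the total alignment columns
#' (gap columns included), the metric behind the 97% OTU threshold.
#'
#' @param a,b non-empty DNA strings (case-insensitive).
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("ACGT", "ACGT")   # 1
#' pairwiseIdentity("AAAA", "TTTT")   # 0
#' @export
pairwiseIdentity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (a <= b) .nwIdentity(a, b)$identity else .nwIdentity(b, a)$identity
}

#' Greedy OTU clustering at an identity threshold
#'
#' De novo mode processes sequences in decreasing length order (ties broken
#' by lexicographic id): each sequence joins the first existing centroid (in
#' founding order) with identity at or above the threshold, otherwise it
#' founds a new centroid. Closed-reference mode assigns each sequence to the
#' best-matching reference centroid at or above the threshold, otherwise it
#' goes to the unassigned pool. Identities come from [pairwiseIdentity()].
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences;
#'   names are the sequence ids.
#' @param identityThreshold identity threshold in (0, 1\], default 0.97.
#' @param mode `"de_novo"` or `"closed_reference"`.
#' @param reference named sequences of reference centroids
#'   (closed-reference mode only).
#' @return A [ClusterResult].
#' @examples
#' seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTTTTTTT")
#' greedyCluster(seqs, identityThreshold = 0.97)
#' @export
greedyCluster <- function(seqs, identityThreshold = 0.97,
                          mode = c("de_novo", "closed_reference"),
                          reference = NULL) {
  mode <- match.arg(mode)
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("'identityThreshold' must lie in (0, 1]")
  seqs <- setNames(toupper(as.character(seqs)), names(seqs))
  if (is.null(names(seqs)) && length(seqs))
    stop("'seqs' must be named")
  if (mode == "closed_reference") {
    if (is.null(reference)) stop("closed-reference mode needs 'reference'")
    reference <- setNames(toupper(as.character(reference)), names(reference))
    if (is.null(names(reference))) stop("'reference' must be named")
  } else if (!is.null(reference)) {
    stop("de novo mode takes no 'reference'")
  }
  empty <- data.frame(member_id = character(0), centroid_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (!length(seqs))
    return(new("ClusterResult", membership = empty, centroids = character(0),
               unassigned = character(0),
               identityThreshold = identityThreshold, mode = mode))

  if (mode == "de_novo") {
    ord <- order(-nchar(seqs), names(seqs), method = "radix")
    ids <- names(seqs)[ord]
    sq <- unname(seqs[ord])
    centroids <- character(0)
    centroidSeqs <- character(0)
    mem <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      joined <- FALSE
      for (k in seq_along(centroids)) {
        idt <- .nwIdentityMany(sq[i], centroidSeqs[k])
        if (idt >= identityThreshold) {
          mem[[i]] <- data.frame(member_id = ids[i],
                                 centroid_id = centroids[k],
                                 identity = idt, stringsAsFactors = FALSE)
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        centroids <- c(centroids, ids[i])
        centroidSeqs <- c(centroidSeqs, sq[i])
        mem[[i]] <- data.frame(member_id = ids[i], centroid_id = ids[i],
                               identity = 1, stringsAsFactors = FALSE)
      }
    }
    membership <- do.call(rbind, mem)
    new("ClusterResult", membership = membership, centroids = centroids,
        unassigned = character(0), identityThreshold = identityThreshold,
        mode = mode)
  } else {
    refIds <- names(reference)
    mem <- vector("list", length(seqs))
    unassigned <- character(0)
    for (i in seq_along(seqs)) {
      idt <- .nwIdentityMany(unname(seqs[i]), unname(reference))
      best <- which.max(idt)
      if (idt[best] >= identityThreshold) {
        mem[[i]] <- data.frame(member_id = names(seqs)[i],
                               centroid_id = refIds[best],
                               identity = idt[best], stringsAsFactors = FALSE)
      } else {
        unassigned <- c(unassigned, names(seqs)[i])
      }
    }
    membership <- do.call(rbind, mem[!vapply(mem, is.null, logical(1))])
    if (is.null(membership)) membership <- empty
    new("ClusterResult", membership = membership,
        centroids = refIds[refIds %in% membership$centroid_id],
        unassigned = unassigned, identityThreshold = identityThreshold,
        mode = mode)
  }
}

#' Write cluster membership to TSV
#'
#' @param result a [ClusterResult].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMembershipTsv <- function(result, path) {
  utils::write.table(clusterMembership(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write centroid sequences to FASTA
#'
#' @param result a [ClusterResult].
#' @param seqs the named input sequences the clustering was run on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCentroidsFasta <- function(result, seqs, path) {
  ids <- clusterCentroids(result)
  x <- Biostrings::DNAStringSet(toupper(as.character(seqs[ids])))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
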