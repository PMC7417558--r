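#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Confidence thresholds for homology-hit filtering
#'
#' Container for the four numeric confidence rules and the banned title
#' keywords applied to tabular homology hits before taxonomy adjudication.
#' Defaults are the conservative settings used for port-survey COI/23S data:
#' alignment length >= 200 nt, identity >= 90%, query coverage exactly 100%,
#' no gaps, and removal of hits whose subject title contains the words
#' "uncultured", "unidentified", "unclassified" or "environmental".
#'
#' @slot minAlignmentLength minimum aligned length in bases.
#' @slot minPident minimum percent identity.
#' @slot requiredQcovs required percent query coverage (hits must equal it).
#' @slot maxGaps maximum number of gaps tolerated.
#' @slot bannedTitleKeywords words that disqualify a hit when present
#'   (case-insensitive, whole word) in its subject title.
#' @seealso [filterThresholds()] for the user constructor.
#' @exportClass FilterThresholds
setClass("FilterThresholds",
  representation(
    minAlignmentLength = "numeric",
    minPident = "numeric",
    requiredQcovs = "numeric",
    maxGaps = "numeric",
    bannedTitleKeywords = "character"
  )
)

setValidity("FilterThresholds", function(object) {
  num <- c(object@minAlignmentLength, object@minPident,
           object@requiredQcovs, object@maxGaps)
  if (length(object@minAlignmentLength) != 1L || length(object@minPident) != 1L ||
      length(object@requiredQcovs) != 1L || length(object@maxGaps) != 1L)
    return("all numeric thresholds must be length 1")
  if (any(!is.finite(num)))
    return("all numeric thresholds must be finite")
  TRUE
})

#' @param minAlignmentLength,minPident,requiredQcovs,maxGaps,bannedTitleKeywords
#'   see the corresponding slots.
#' @return A `FilterThresholds` object.
#' @examples
#' filterThresholds()
#' filterThresholds(minPident = 95)
#' @rdname FilterThresholds-class
#' @export
filterThresholds <- function(minAlignmentLength = 200,
                             minPident = 90,
                             requiredQcovs = 100,
                             maxGaps = 0,
                             bannedTitleKeywords = c("uncultured", "unidentified",
                                                     "unclassified", "environmental")) {
  new("FilterThresholds",
      minAlignmentLength = as.numeric(minAlignmentLength),
      minPident = as.numeric(minPident),
      requiredQcovs = as.numeric(requiredQcovs),
      maxGaps = as.numeric(maxGaps),
      bannedTitleKeywords = as.character(bannedTitleKeywords))
}

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds:\n",
      "  alignment length >= ", object@minAlignmentLength, "\n",
      "  percent identity >= ", object@minPident, "\n",
      "  query coverage   == ", object@requiredQcovs, "\n",
      "  gaps             <= ", object@maxGaps, "\n",
      "  banned keywords: ", paste(object@bannedTitleKeywords, collapse = ", "),
      "\n", sep = "")
})

#' Result of greedy OTU clustering
#'
#' Holds the membership map produced by [greedyCluster()]: for every input
#' sequence, the centroid it joined and its percent identity to that centroid
#' (as a fraction), plus, in closed-reference mode, the ids that matched no
#' reference centroid at the threshold.
#'
#' @slot membership data.frame with columns `member_id`, `centroid_id`,
#'   `identity` (fraction in \[0, 1\]).
#' @slot centroids character vector of centroid ids in founding order.
#' @slot unassigned character vector of unclustered ids (closed-reference).
#' @slot identityThreshold the identity threshold used.
#' @slot mode `"de_novo"` or `"closed_reference"`.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    membership = "data.frame",
    centroids = "character",
    unassigned = "character",
    identityThreshold = "numeric",
    mode = "character"
  )
)

setValidity("ClusterResult", function(object) {
  m <- object@membership
  if (!all(c("member_id", "centroid_id", "identity") %in% names(m)))
    return("membership must have columns member_id, centroid_id, identity")
  if (anyDuplicated(m$member_id))
    return("clusters must be disjoint: duplicated member_id")
  if (nrow(m) && any(m$identity < object@identityThreshold - 1e-12))
    return("every member identity must be >= the identity threshold")
  if (!object@mode %in% c("de_novo", "closed_reference"))
    return("mode must be 'de_novo' or 'closed_reference'")
  if (length(intersect(m$member_id, object@unassigned)))
    return("a sequence cannot be both clustered and unassigned")
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult (", object@mode, ", threshold ",
      object@identityThreshold, ")\n", sep = "")
  cat("  ", length(object@centroids), " clusters, ",
      nrow(object@membership), " members, ",
      length(object@unassigned), " unassigned\n", sep = "")
})

#' Sample-by-OTU abundance matrix with group labels
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' single `counts` assay stores non-negative integer OTU counts (OTUs in rows,
#' samples in columns) and whose column data carries the experimental group of
#' each sample (e.g. `painted` vs `bare` panels).
#'
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("AbundanceMatrix needs a 'counts' assay")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("counts must be non-negative")
  if (any(cts != round(cts))) return("counts must be integers")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain a 'group' column")
  TRUE
})

#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows and OTUs in columns (row names = sample ids, col names = OTU ids).
#' @param group character/factor of group labels, one per sample.
#' @return An `AbundanceMatrix`.
#' @examples
#' m <- matrix(rpois(12, 5), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("otu", 1:3)))
#' AbundanceMatrix(m, group = c("painted", "painted", "bare", "bare"))
#' @rdname AbundanceMatrix-class
#' @export
AbundanceMatrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  if (length(group) != nrow(counts))
    stop("'group' must have one label per sample (row of 'counts')")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = t(counts)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = rownames(counts)))
  new("AbundanceMatrix", se)
}

setMethod("show", "AbundanceMatrix", function(object) {
  g <- table(groupLabels(object))
  cat("AbundanceMatrix: ", ncol(object), " samples x ", nrow(object),
      " OTUs\n", sep = "")
  cat("  groups:", paste(names(g), g, sep = "=", collapse = ", "), "\n")
})

#' Image stack for one monitored panel
#'
#' Grayscale intensity stack (depth x height x width) of a photographed
#' settlement panel, optionally with a rectangular region of interest and the
#' planted true fouling coverage when the stack is synthetic.
#'
#' @slot pixels numeric array `depth x height x width` of intensities.
#' @slot bitDepth 8 or 16; fixes the intensity range for [toGray8()].
#' @slot roi integer(4) `c(x0, y0, x1, y1)`, 0-based half-open, or
#'   `integer(0)` for the whole frame.
#' @slot trueCoverage planted foreground fraction (NA for real images).
#' @exportClass PanelImageStack
setClass("PanelImageStack",
  representation(
    pixels = "array",
    bitDepth = "numeric",
    roi = "integer",
    trueCoverage = "numeric"
  )
)

setValidity("PanelImageStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be a depth x height x width array")
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L)
    return("all stack dimensions must be positive")
  if (!object@bitDepth %in% c(8, 16)) return("bitDepth must be 8 or 16")
  if (length(object@roi) && length(object@roi) != 4L)
    return("roi must be integer(0) or c(x0, y0, x1, y1)")
  if (length(object@roi) == 4L) {
    r <- object@roi
    if (r[1] < 0L || r[2] < 0L || r[3] > d[3] || r[4] > d[2] ||
        r[3] <= r[1] || r[4] <= r[2])
      return("roi must be a non-empty rectangle within the image bounds")
  }
  if (length(object@trueCoverage) == 1L && !is.na(object@trueCoverage) &&
      (object@trueCoverage < 0 || object@trueCoverage > 1))
    return("trueCoverage must be in [0, 1]")
  TRUE
})

#' @param pixels,bitDepth,roi,trueCoverage see the slots.
#' @return A `PanelImageStack`.
#' @rdname PanelImageStack-class
#' @export
PanelImageStack <- function(pixels, bitDepth = 8, roi = integer(0),
                            trueCoverage = NA_real_) {
  if (length(dim(pixels)) == 2L)
    pixels <- array(pixels, dim = c(1L, dim(pixels)))
  new("PanelImageStack", pixels = pixels, bitDepth = as.numeric(bitDepth),
      roi = as.integer(roi), trueCoverage = as.numeric(trueCoverage))
}

setMethod("show", "PanelImageStack", function(object) {
  d <- dim(object@pixels)
  cat("PanelImageStack: ", d[1], " slice(s) of ", d[2], "x", d[3],
      " (", object@bitDepth, "-bit)\n", sep = "")
  if (!is.na(object@trueCoverage))
    cat("  planted true coverage: ",
        format(100 * object@trueCoverage, digits = 4), "%\n", sep = "")
})

#' Permutational multivariate ANOVA result
#'
#' One-way PERMANOVA on a dissimilarity matrix: sums of squares partition,
#' pseudo-F, R-squared, and a permutation p-value (sampled relabellings, or
#' exhaustive enumeration when the number of distinct two-group relabellings
#' does not exceed the permutation budget).
#'
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  representation(
    pseudoF = "numeric", R2 = "numeric", pValue = "numeric",
    dfBetween = "numeric", dfWithin = "numeric",
    ssBetween = "numeric", ssWithin = "numeric", ssTotal = "numeric",
    nPermutations = "numeric", seed = "numeric", pMethod = "character"
  )
)

setValidity("PermanovaResult", function(object) {
  if (abs(object@ssBetween + object@ssWithin - object@ssTotal) > 1e-9)
    return("SS_between + SS_within must equal SS_total")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  if (object@R2 < 0 || object@R2 > 1) return("R2 must lie in [0, 1]")
  TRUE
})

setMethod("show", "PermanovaResult", function(object) {
  msB <- object@ssBetween / object@dfBetween
  msW <- object@ssWithin / object@dfWithin
  tab <- data.frame(
    Df = c(object@dfBetween, object@dfWithin,
           object@dfBetween + object@dfWithin),
    SumsOfSqs = c(object@ssBetween, object@ssWithin, object@ssTotal),
    MeanSqs = c(msB, msW, NA),
    F.Model = c(object@pseudoF, NA, NA),
    R2 = c(object@R2, object@ssWithin / object@ssTotal, 1),
    `Pr..F.` = c(object@pValue, NA, NA),
    row.names = c("Treatment", "Residuals", "Total"))
  cat("PERMANOVA (", object@pMethod, ", ", object@nPermutations,
      " permutations)\n", sep = "")
  print(format(tab, digits = 5))
})

#' Multivariate dispersion homogeneity result
#'
#' Distances of samples to their group centroid in the principal-coordinates
#' embedding of a dissimilarity matrix (negative eigenvalue axes subtracted in
#' the squared distances), with a one-way F statistic on those distances and a
#' permutation p-value.
#'
#' @exportClass BetadisperResult
setClass("BetadisperResult",
  representation(
    distances = "numeric", groups = "character",
    groupMeanDistances = "numeric", fStat = "numeric", pValue = "numeric",
    eigenvalues = "numeric", nPermutations = "numeric", seed = "numeric"
  )
)

setValidity("BetadisperResult", function(object) {
  if (any(object@distances < 0)) return("centroid distances must be >= 0")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  TRUE
})

setMethod("show", "BetadisperResult", function(object) {
  cat("Homogeneity of multivariate dispersions (",
      object@nPermutations, " permutations)\n", sep = "")
  cat("  mean distance to centroid:\n")
  print(round(object@groupMeanDistances, 4))
  cat("  F = ", format(object@fStat, digits = 5),
      ", p = ", format(object@pValue, digits = 4), "\n", sep = "")
})
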