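#' Group labels of an abundance matrix
#'
#' @param x an [AbundanceMatrix].
#' @return Character vector of one group label per sample.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "AbundanceMatrix", function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
})

#' Counts of an abundance matrix, samples in rows
#'
#' Returns the count table in the samples-by-OTU orientation used by the
#' diversity and ordination functions.
#'
#' @param x an [AbundanceMatrix].
#' @return Integer matrix, samples in rows, OTUs in columns.
#' @export
setGeneric("abundanceCounts", function(x) standardGeneric("abundanceCounts"))

#' @rdname abundanceCounts
#' @export
setMethod("abundanceCounts", "AbundanceMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' Sample identifiers
#' @param x an [AbundanceMatrix].
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "AbundanceMatrix", function(x) colnames(x))

#' OTU identifiers
#' @param x an [AbundanceMatrix].
#' @return Character vector of OTU ids.
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname otuIds
#' @export
setMethod("otuIds", "AbundanceMatrix", function(x) rownames(x))

#' Planted true coverage of a synthetic panel stack
#' @param x a [PanelImageStack].
#' @return Foreground fraction in \[0, 1\], or `NA` for real images.
#' @export
setGeneric("trueCoverage", function(x) standardGeneric("trueCoverage"))

#' @rdname trueCoverage
#' @export
setMethod("trueCoverage", "PanelImageStack", function(x) x@trueCoverage)

#' Pixel array of a panel stack
#' @param x a [PanelImageStack].
#' @return Numeric array `depth x height x width`.
#' @export
setGeneric("stackPixels", function(x) standardGeneric("stackPixels"))

#' @rdname stackPixels
#' @export
setMethod("stackPixels", "PanelImageStack", function(x) x@pixels)

#' Cluster membership table
#' @param x a [ClusterResult].
#' @return data.frame with columns `member_id`, `centroid_id`, `identity`.
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname clusterMembership
#' @export
setMethod("clusterMembership", "ClusterResult", function(x) x@membership)

#' Centroid ids of a clustering
#' @param x a [ClusterResult].
#' @return Character vector of centroid ids in founding order.
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))

#' @rdname clusterCentroids
#' @export
setMethod("clusterCentroids", "ClusterResult", function(x) x@centroids)

#' Unassigned sequence ids of a closed-reference clustering
#' @param x a [ClusterResult].
#' @return Character vector of ids that matched no reference centroid.
#' @export
setGeneric("clusterUnassigned", function(x) standardGeneric("clusterUnassigned"))

#' @rdname clusterUnassigned
#' @export
setMethod("clusterUnassigned", "ClusterResult", function(x) x@unassigned)

#' Permutation p-value
#' @param x a [PermanovaResult] or [BetadisperResult].
#' @return The permutation p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "PermanovaResult", function(x) x@pValue)

#' @rdname pValue
#' @export
setMethod("pValue", "BetadisperResult", function(x) x@pValue)
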