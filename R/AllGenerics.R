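#' @rdname HoxCluster-class
#' @param object,x a package object.
#' @export
setGeneric("organism", function(object) standardGeneric("organism"))

#' @rdname HoxCluster-class
#' @export
setGeneric("geneNumbers", function(object) standardGeneric("geneNumbers"))

#' @rdname HoxCluster-class
#' @export
setGeneric("geneLabels", function(object) standardGeneric("geneLabels"))

#' @rdname HoxCluster-class
#' @export
setGeneric("distancesKbp", function(object) standardGeneric("distancesKbp"))

#' @rdname HoxCluster-class
#' @export
setGeneric("geneLengthsKbp",
           function(object) standardGeneric("geneLengthsKbp"))

#' @rdname HoxCluster-class
#' @export
setGeneric("fixedPosteriorEnd",
           function(object) standardGeneric("fixedPosteriorEnd"))

#' @rdname HoxCluster-class
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname clusterSpan
#' @export
setGeneric("clusterSpan", function(cluster) standardGeneric("clusterSpan"))

#' @rdname clusterStats
#' @export
setGeneric("clusterStats", function(cluster) standardGeneric("clusterStats"))

#' @rdname restrictToGenes
#' @export
setGeneric("restrictToGenes",
           function(cluster, keep) standardGeneric("restrictToGenes"))

#' @rdname genePositions
#' @export
setGeneric("genePositions", function(cluster) standardGeneric("genePositions"))

#' @rdname computeFPR
#' @export
setGeneric("computeFPR",
           function(cluster, l = 100) standardGeneric("computeFPR"))

#' @rdname segmentStats
#' @export
setGeneric("segmentStats",
           function(perturbed) standardGeneric("segmentStats"))

#' @rdname applyManipulation
#' @export
setGeneric("applyManipulation",
           function(cluster, m) standardGeneric("applyManipulation"))

#' @rdname intensities
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
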