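#' @rdname CommunityTimeSeries-accessors
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname CommunityTimeSeries-accessors
#' @export
setGeneric("missingDates", function(x) standardGeneric("missingDates"))

#' @rdname CommunityTimeSeries-accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname CommunityTimeSeries-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname CommunityTimeSeries-accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname SOMModel-accessors
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @rdname SOMModel-accessors
#' @export
setGeneric("bmu", function(x) standardGeneric("bmu"))

#' @rdname SOMModel-accessors
#' @export
setGeneric("quantizationError", function(x) standardGeneric("quantizationError"))

#' @rdname SOMModel-accessors
#' @export
setGeneric("topographicError", function(x) standardGeneric("topographicError"))

#' @rdname ClusterPartition-accessors
#' @export
setGeneric("rawLabels", function(x) standardGeneric("rawLabels"))

#' @rdname ClusterPartition-accessors
#' @export
setGeneric("smoothedLabels", function(x) standardGeneric("smoothedLabels"))

#' @rdname ClusterPartition-accessors
#' @export
setGeneric("exemptions", function(x) standardGeneric("exemptions"))

#' @rdname ClusterPartition-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
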