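#' @rdname ObservationTable-accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname ObservationTable-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname ObservationTable-accessors
#' @export
setGeneric("nObservations", function(x) standardGeneric("nObservations"))

#' @rdname ObservationTable-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname ObservationTable-accessors
#' @export
setGeneric("blankSamples", function(x) standardGeneric("blankSamples"))

#' @rdname ObservationTable-accessors
#' @export
setGeneric("hasStats", function(x) standardGeneric("hasStats"))

#' @rdname FilterThresholds-accessors
#' @export
setGeneric("thresholdReads", function(x) standardGeneric("thresholdReads"))

#' @rdname FilterThresholds-accessors
#' @export
setGeneric("thresholdReadprop",
           function(x) standardGeneric("thresholdReadprop"))

#' @rdname FilterThresholds-accessors
#' @export
setGeneric("thresholdNorm", function(x) standardGeneric("thresholdNorm"))

#' @rdname FilterThresholds-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname OtuAssignment-accessors
#' @export
setGeneric("otuMapping", function(x) standardGeneric("otuMapping"))

#' @rdname OtuAssignment-accessors
#' @export
setGeneric("otuRepresentatives",
           function(x) standardGeneric("otuRepresentatives"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("simulationParams",
           function(x) standardGeneric("simulationParams"))
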