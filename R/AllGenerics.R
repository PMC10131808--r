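#' @rdname MultichannelRecord-class
#' @param object,x an object.
#' @export
setGeneric("recordData", function(x) standardGeneric("recordData"))

#' @rdname MultichannelRecord-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname MultichannelRecord-class
#' @export
setGeneric("copdStage", function(x) standardGeneric("copdStage"))

#' @rdname MultichannelRecord-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname MultichannelRecord-class
#' @export
setGeneric("institution", function(x) standardGeneric("institution"))

#' @rdname FractionalModel-class
#' @export
setGeneric("couplingMatrix", function(x) standardGeneric("couplingMatrix"))

#' @rdname FractionalModel-class
#' @export
setGeneric("fractionalOrders", function(x) standardGeneric("fractionalOrders"))

#' @rdname HurstCurve-class
#' @export
setGeneric("hurstExponents", function(x) standardGeneric("hurstExponents"))

#' @rdname ScalingSurface-class
#' @export
setGeneric("focusPoint", function(x) standardGeneric("focusPoint"))

#' @rdname StagedDataset-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname StagedDataset-class
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname EvalReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
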