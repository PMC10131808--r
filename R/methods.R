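# Accessors and show() methods for the central S4 classes.

#' @rdname MultichannelRecord-class
#' @aliases recordData channelLabels copdStage patientId institution
#' @export
setMethod("recordData", "MultichannelRecord", function(x) x@data)

#' @rdname MultichannelRecord-class
#' @export
setMethod("channelLabels", "MultichannelRecord", function(x) x@channels)

#' @rdname MultichannelRecord-class
#' @export
setMethod("copdStage", "MultichannelRecord", function(x) x@stage)

#' @rdname MultichannelRecord-class
#' @export
setMethod("patientId", "MultichannelRecord", function(x) x@patientId)

#' @rdname MultichannelRecord-class
#' @export
setMethod("institution", "MultichannelRecord", function(x) x@institution)

setMethod("show", "MultichannelRecord", function(object) {
  cat("MultichannelRecord", object@recordId, "\n",
      " ", nrow(object@data), "channels x", ncol(object@data), "samples\n",
      "  patient:", object@patientId,
      " institution:", object@institution,
      " stage:", ifelse(is.na(object@stage), "unknown", object@stage), "\n")
})

#' @rdname FractionalModel-class
#' @aliases couplingMatrix fractionalOrders
#' @export
setMethod("couplingMatrix", "FractionalModel", function(x) x@A)

#' @rdname FractionalModel-class
#' @export
setMethod("fractionalOrders", "FractionalModel", function(x) x@alpha)

setMethod("show", "FractionalModel", function(object) {
  cat("FractionalModel: n =", nrow(object@A), " p =", object@p,
      " memoryJ =", object@memoryJ, "\n",
      " alpha:", paste(sprintf("%.3f", object@alpha), collapse = " "), "\n",
      " residual:", if (length(object@residualHistory))
        sprintf("%.4g", tail(object@residualHistory, 1)) else "NA",
      " converged:", object@converged, "\n")
})

#' @rdname ScalingSurface-class
#' @aliases focusPoint
#' @export
setMethod("focusPoint", "ScalingSurface", function(x) x@focus)

setMethod("show", "ScalingSurface", function(object) {
  cat("ScalingSurface: ", length(object@qGrid), " q values x ",
      length(object@scales), " scales (L = ", object@L, ")\n",
      "  focus S(q, L) = ", sprintf("%.5g", object@focus), "\n", sep = "")
})

#' @rdname HurstCurve-class
#' @aliases hurstExponents
#' @export
setMethod("hurstExponents", "HurstCurve", function(x) {
  setNames(x@H, paste0("q=", x@qGrid))
})

setMethod("show", "HurstCurve", function(object) {
  cat("HurstCurve (", object@fitMode, ", n = ", object@nCurves, "):\n", sep = "")
  print(round(rbind(q = object@qGrid, H = object@H, se = object@stderr), 4))
})

#' @rdname StagedDataset-class
#' @aliases featureMatrix stageLabels
#' @export
setMethod("featureMatrix", "StagedDataset", function(x) x@features)

#' @rdname StagedDataset-class
#' @export
setMethod("stageLabels", "StagedDataset", function(x) x@labels)

setMethod("show", "StagedDataset", function(object) {
  cat("StagedDataset:", nrow(object@features), "records x",
      ncol(object@features), "features (", object@preset, ")\n",
      " stages:", paste(names(table(object@labels)), table(object@labels),
                        sep = ":", collapse = " "), "\n",
      " institutions:", paste(unique(object@institutions), collapse = " "),
      " normalized:", object@normalized, "\n")
})

#' @rdname EvalReport-class
#' @aliases confusionMatrix perClassMetrics
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", object@protocol, "): accuracy ",
      sprintf("%.2f%%", 100 * object@accuracyMean),
      if (is.finite(object@accuracySd))
        sprintf(" +/- %.2f%%", 100 * object@accuracySd) else "",
      ", macro AUROC ", sprintf("%.3f", object@auroc), "\n", sep = "")
  cat("confusion (rows = truth):\n"); print(object@confusion)
})

setMethod("show", "NetSpec", function(object) {
  cat("NetSpec:", object@inputDim, "->",
      paste(object@hidden, collapse = " -> "), "->", object@nClasses,
      "| dropout", object@dropoutRate, "lr", object@learningRate,
      "epochs", object@epochs, "batch", object@batchSize, "\n")
})

setMethod("show", "FddlmModel", function(object) {
  cat("FddlmModel (trained:", object@trained, ")\n"); show(object@spec)
})
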