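#' @import methods
#' @importFrom stats approx coef fft lm lm.fit median predict qt
#'   rnorm runif sd setNames
#' @importFrom utils head modifyList read.csv tail write.csv
#' @importFrom tools md5sum
#' @useDynLib fddlm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Channel presets
#'
#' Canonical channel rosters of the two portable devices the pipeline
#' supports: the 12-channel NOX-style polygraph and the 6-channel Porti-style
#' polygraph. Flattened coupling matrices from them have 144 and 36 entries.
#'
#' @param preset `"nox12"` or `"porti6"`.
#' @return Character vector of canonical channel labels.
#' @examples
#' channelPreset("porti6")
#' @export
channelPreset <- function(preset = c("nox12", "porti6")) {
  preset <- match.arg(preset)
  switch(preset,
    nox12 = c("Thorax", "Abdomen", "SpO2", "SpO2 B-B", "Pulse",
              "Plethysmograph", "Nasal Pressure", "RIP Sum", "Activity",
              "Position", "Flow", "Resp Rate"),
    porti6 = c("Flow", "SpO2", "Pulse", "Plethysmograph", "Thorax", "Abdomen"))
}

#' MultichannelRecord: one labeled physiological recording
#'
#' Container for a single multichannel recording: a channels x samples data
#' matrix plus the metadata the evaluation protocols need (patient, clinic,
#' COPD stage). Stage is an integer 0 (no COPD) to 4 (very severe), or
#' `NA_integer_` when unknown (inference-only records).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot channels ordered channel labels, one per data row.
#' @slot recordId,patientId,institution character identifiers.
#' @slot stage integer 0-4 or NA.
#' @slot samplingNote free-text note on the nominal rate or resampling.
#' @exportClass MultichannelRecord
setClass("MultichannelRecord",
  representation(data = "matrix", channels = "character",
                 recordId = "character", patientId = "character",
                 institution = "character", stage = "integer",
                 samplingNote = "character"),
  prototype(samplingNote = "nominal"))

setValidity("MultichannelRecord", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "data row count must equal number of channel labels")
  if (!is.na(object@stage) && (object@stage < 0L || object@stage > 4L))
    msg <- c(msg, "stage must be in 0..4 or NA")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must contain no non-finite samples")
  if (length(msg)) msg else TRUE
})

#' ScalingSurface: moment-wise MF-DFA scaling function
#'
#' Holds S(q, s) over the moment grid q and window scales s, together with
#' the focus estimate S(q, L) at the full signal length L (a single globally
#' detrended window, hence independent of q by construction).
#'
#' @slot S numeric matrix, length(qGrid) x length(scales).
#' @slot qGrid,scales numeric vectors.
#' @slot L full signal length.
#' @slot focus the focus-point estimate S(q, L).
#' @slot nWindows windows per scale (floor(L/s)).
#' @slot droppedWindows count of zero-fluctuation windows excluded from the
#'   negative-q moment sums.
#' @exportClass ScalingSurface
setClass("ScalingSurface",
  representation(S = "matrix", qGrid = "numeric", scales = "numeric",
                 L = "integer", focus = "numeric", nWindows = "integer",
                 droppedWindows = "integer"),
  prototype(droppedWindows = 0L))

setValidity("ScalingSurface", function(object) {
  msg <- character()
  if (nrow(object@S) != length(object@qGrid))
    msg <- c(msg, "S must have one row per q")
  if (ncol(object@S) != length(object@scales))
    msg <- c(msg, "S must have one column per scale")
  if (is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' HurstCurve: generalized Hurst exponent over a moment grid
#'
#' H(q) with per-q regression standard errors and 95% intervals. For a group
#' summary (see [groupHurstBand()]) the interval is the t-based band on the
#' per-q mean across signals and `nCurves` records the group size.
#'
#' @slot qGrid,H,stderr numeric vectors of equal length.
#' @slot ci95 2 x length(qGrid) matrix (rows: lower, upper).
#' @slot fitMode `"per_q_ols"` or `"focus_regression"`.
#' @slot nCurves number of signals summarized (1 for a single fit).
#' @exportClass HurstCurve
setClass("HurstCurve",
  representation(qGrid = "numeric", H = "numeric", stderr = "numeric",
                 ci95 = "matrix", fitMode = "character", nCurves = "integer"),
  prototype(fitMode = "per_q_ols", nCurves = 1L))

setValidity("HurstCurve", function(object) {
  k <- length(object@qGrid)
  msg <- character()
  if (length(object@H) != k || length(object@stderr) != k)
    msg <- c(msg, "H and stderr must match qGrid length")
  if (!all(dim(object@ci95) == c(2L, k)))
    msg <- c(msg, "ci95 must be a 2 x length(qGrid) matrix")
  if (length(msg)) msg else TRUE
})

#' FractionalModel: identified discrete fractional-order linear system
#'
#' The matrix tuple (alpha, A, B, C) of the fractional coupled model plus the
#' estimated unknown-input sequence U and fit diagnostics. The input
#' dimension p is strictly smaller than the state dimension n; C is the
#' identity (all channels observed).
#'
#' @slot alpha per-channel fractional orders (length n).
#' @slot A n x n coupling matrix.
#' @slot B n x p input matrix (0 columns when p = 0).
#' @slot C n x n output matrix (identity).
#' @slot U p x T estimated unknown-input sequence.
#' @slot p input dimension.
#' @slot residualHistory per-iteration residual norms of the alternating fit.
#' @slot memoryJ Grünwald-Letnikov truncation length used.
#' @slot converged logical.
#' @exportClass FractionalModel
setClass("FractionalModel",
  representation(alpha = "numeric", A = "matrix", B = "matrix", C = "matrix",
                 U = "matrix", p = "integer", residualHistory = "numeric",
                 memoryJ = "integer", converged = "logical"),
  prototype(p = 0L, converged = TRUE))

setValidity("FractionalModel", function(object) {
  n <- nrow(object@A)
  msg <- character()
  if (ncol(object@A) != n) msg <- c(msg, "A must be square")
  if (length(object@alpha) != n) msg <- c(msg, "alpha must have length n")
  if (object@p >= n) msg <- c(msg, "input dimension p must be < n")
  if (object@memoryJ < 1L) msg <- c(msg, "memoryJ must be >= 1")
  if (length(msg)) msg else TRUE
})

#' StagedDataset: per-record feature table with labels and groups
#'
#' Rows are records, columns the flattened coupling-matrix features (144 for
#' nox12, 36 for porti6). Carries the stage labels, patient IDs and
#' institutions needed by the k-fold / hold-out protocols.
#'
#' @slot features records x n^2 numeric matrix.
#' @slot labels integer stages, one per record.
#' @slot patientIds,institutions,recordIds character, one per record.
#' @slot preset channel preset name.
#' @slot normalized logical: TRUE once min-max scaled to [0, 1].
#' @exportClass StagedDataset
setClass("StagedDataset",
  representation(features = "matrix", labels = "integer",
                 patientIds = "character", institutions = "character",
                 recordIds = "character", preset = "character",
                 normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("StagedDataset", function(object) {
  n <- nrow(object@features)
  msg <- character()
  if (length(object@labels) != n || length(object@patientIds) != n ||
      length(object@institutions) != n || length(object@recordIds) != n)
    msg <- c(msg, "labels, patientIds, institutions, recordIds must have one entry per record")
  if (length(msg)) msg else TRUE
})

#' EvalReport: confusion matrix and per-class metrics
#'
#' Result of one evaluation protocol: aggregate confusion matrix over test
#' folds, one-vs-rest per-class sensitivity/specificity/precision, accuracy
#' mean and sd across folds, macro AUROC, and the misclassified fraction.
#'
#' @slot confusion K x K count matrix (rows: truth, columns: prediction).
#' @slot perClass 3 x K matrix (sensitivity, specificity, precision); NA where
#'   a ratio is undefined.
#' @slot accuracyMean,accuracySd,auroc,misclassifiedFraction numeric scalars.
#' @slot foldAccuracies per-fold test accuracies.
#' @slot protocol description of the protocol that produced the report.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(confusion = "matrix", perClass = "matrix",
                 accuracyMean = "numeric", accuracySd = "numeric",
                 auroc = "numeric", misclassifiedFraction = "numeric",
                 foldAccuracies = "numeric", protocol = "character"),
  prototype(protocol = "kfold"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (any(object@confusion < 0)) msg <- c(msg, "confusion entries must be nonnegative")
  ok <- object@perClass[is.finite(object@perClass)]
  if (length(ok) && (any(ok < 0) || any(ok > 1)))
    msg <- c(msg, "per-class rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NetSpec: feedforward classifier architecture and training setup
#'
#' Describes the staging network: input_dim -> hidden layers (rectifier
#' activations, dropout after each) -> softmax output, trained with rmsprop
#' on the categorical cross-entropy.
#'
#' @slot inputDim,nClasses,epochs,batchSize,seed integers.
#' @slot hidden ordered hidden-layer sizes.
#' @slot dropoutRate dropout probability in [0, 1).
#' @slot learningRate rmsprop learning rate.
#' @exportClass NetSpec
setClass("NetSpec",
  representation(inputDim = "integer", hidden = "integer",
                 nClasses = "integer", dropoutRate = "numeric",
                 learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", seed = "integer"))

setValidity("NetSpec", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (any(object@hidden <= 0L)) msg <- c(msg, "hidden sizes must be positive")
  if (object@inputDim <= 0L) msg <- c(msg, "inputDim must be positive")
  if (length(msg)) msg else TRUE
})

#' FddlmModel: weights of the staging network
#'
#' @slot spec the [NetSpec-class] that built the model.
#' @slot weights list of weight matrices W1..WL.
#' @slot biases list of bias vectors b1..bL.
#' @slot trained logical.
#' @slot lossHistory per-epoch mean training loss.
#' @exportClass FddlmModel
setClass("FddlmModel",
  representation(spec = "NetSpec", weights = "list", biases = "list",
                 trained = "logical", lossHistory = "numeric"),
  prototype(trained = FALSE, lossHistory = numeric()))
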