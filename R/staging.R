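# Evaluation harness: feature normalization, k-fold and institution
# hold-out protocols, linear probe, confusion-matrix metrics and the
# spirometry staging rule.

#' Assemble a staged dataset from records
#'
#' Runs [extractFeature()] on every record and collects features, stage
#' labels, patient IDs and institutions into a [StagedDataset-class].
#'
#' @param records list of [MultichannelRecord-class] objects.
#' @param preset channel preset shared by the records.
#' @param J,p,alpha passed to [extractFeature()].
#' @return a [StagedDataset-class] (not yet normalized).
#' @export
buildStagedDataset <- function(records, preset = c("nox12", "porti6"),
                               J = NULL, p = 0L, alpha = NULL) {
  preset <- match.arg(preset)
  feats <- lapply(records, function(r)
    extractFeature(r, preset,
                   J = if (is.null(J)) ncol(recordData(r)) else J,
                   p = p, alpha = alpha))
  new("StagedDataset",
      features = do.call(rbind, lapply(feats, as.numeric)),
      labels = vapply(records, copdStage, integer(1)),
      patientIds = vapply(records, patientId, character(1)),
      institutions = vapply(records, institution, character(1)),
      recordIds = vapply(records, function(r) r@recordId, character(1)),
      preset = preset, normalized = FALSE)
}

#' Min-max feature normalization fit on training data
#'
#' Per-feature scaling to [0, 1] with the minimum and range of the training
#' table only; held-out tables are scaled with the training scaler and
#' clipped to [0, 1] (clip count returned). Constant training features map
#' to 0 with a warning.
#'
#' @param train numeric training feature matrix.
#' @param others optional list of held-out feature matrices.
#' @return list with `train`, `others`, `scaler` (`min`, `range`) and
#'   `clipped` (count of clipped held-out values).
#' @export
normalizeFeatures <- function(train, others = list()) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training table")
  mn <- apply(train, 2L, min)
  rg <- apply(train, 2L, max) - mn
  const <- rg == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to 0")
    rg[const] <- 1
  }
  scale1 <- function(M) sweep(sweep(as.matrix(M), 2L, mn), 2L, rg, `/`)
  tr <- scale1(train); tr[, const] <- 0
  clipped <- 0L
  oth <- lapply(others, function(M) {
    S <- scale1(M); S[, const] <- 0
    clipped <<- clipped + sum(S < 0 | S > 1)
    pmin(pmax(S, 0), 1)
  })
  list(train = tr, others = oth, scaler = list(min = mn, range = rg),
       clipped = clipped)
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest sensitivity TP/(TP+FN), specificity TN/(TN+FP) and precision
#' TP/(TP+FP) per class; undefined ratios are NA, not 0.
#'
#' @param confusion square nonnegative count matrix, rows = truth.
#' @return 3 x K matrix with rows sensitivity, specificity, precision.
#' @export
metricsFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion entries must be nonnegative")
  if (sum(confusion) == 0) stop("all-zero confusion matrix")
  K <- nrow(confusion)
  tot <- sum(confusion)
  out <- matrix(NA_real_, 3L, K,
                dimnames = list(c("sensitivity", "specificity", "precision"),
                                colnames(confusion) %||% paste0("class", seq_len(K) - 1L)))
  for (c in seq_len(K)) {
    TP <- confusion[c, c]
    FN <- sum(confusion[c, ]) - TP
    FP <- sum(confusion[, c]) - TP
    TN <- tot - TP - FN - FP
    if (TP + FN > 0) out["sensitivity", c] <- TP / (TP + FN)
    if (TN + FP > 0) out["specificity", c] <- TN / (TN + FP)
    if (TP + FP > 0) out["precision", c] <- TP / (TP + FP)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Macro one-vs-rest AUROC from softmax scores; classes absent from the truth
# or with a single level are skipped.
.macroAuroc <- function(y, P, classes) {
  aucs <- vapply(seq_along(classes), function(i) {
    resp <- as.integer(y == classes[i])
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, P[, i], quiet = TRUE,
                                   direction = "<", levels = c(0L, 1L))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

.confusion <- function(truth, pred, classes) {
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  M <- unclass(as.matrix(tab))
  dimnames(M) <- list(paste0("stage", classes), paste0("stage", classes))
  M
}

# Train on (Xtr, ytr), evaluate on (Xte, yte); returns accuracy, confusion,
# auroc. Normalization is fit on the training rows only.
.evalSplit <- function(Xtr, ytr, Xte, yte, spec, classes, epochs) {
  nm <- normalizeFeatures(Xtr, list(Xte))
  if (length(setdiff(classes, unique(ytr))))
    warning("class(es) ", paste(setdiff(classes, unique(ytr)), collapse = ","),
            " absent from a training fold")
  model <- trainFddlm(buildFddlm(spec), nm$train, ytr, epochs = epochs)
  P <- predictFddlm(model, nm$others[[1L]], type = "prob")
  pred <- classes[max.col(P, ties.method = "first")]
  list(accuracy = mean(pred == yte),
       confusion = .confusion(yte, pred, classes),
       auroc = .macroAuroc(yte, P, classes))
}

#' k-fold cross-validation of the staging network
#'
#' Shuffles the dataset (seeded), splits it into k disjoint folds --
#' per-record, or per-patient so that all records of a patient stay in one
#' fold -- trains on k-1 folds and tests on the held-out fold, rotating.
#' Feature normalization is fit per training fold to avoid leakage.
#'
#' @param dataset a [StagedDataset-class] (raw features; normalization is
#'   internal).
#' @param k number of folds (>= 2).
#' @param grouping `"per_record"` or `"per_patient"`.
#' @param spec a [netSpec()]; its `input_dim` must match the feature width.
#' @param seed shuffle seed.
#' @param epochs optional override of `spec@epochs`.
#' @return an [EvalReport-class] aggregated over folds.
#' @export
kfoldEval <- function(dataset, k = 5L, grouping = c("per_record",
                                                    "per_patient"),
                      spec = netSpec(ncol(featureMatrix(dataset))),
                      seed = 1L, epochs = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(is(dataset, "StagedDataset"), k >= 2L)
  X <- featureMatrix(dataset); y <- stageLabels(dataset)
  classes <- 0:4
  set.seed(seed)
  fold <- integer(nrow(X))
  if (grouping == "per_record") {
    fold <- sample(rep_len(seq_len(k), nrow(X)))
  } else {
    pats <- unique(dataset@patientIds)
    pf <- setNames(sample(rep_len(seq_len(k), length(pats))), pats)
    fold <- pf[dataset@patientIds]
  }
  res <- lapply(seq_len(k), function(f) {
    te <- fold == f
    sp <- spec; sp@seed <- spec@seed + f
    .evalSplit(X[!te, , drop = FALSE], y[!te],
               X[te, , drop = FALSE], y[te], sp, classes, epochs)
  })
  conf <- Reduce(`+`, lapply(res, `[[`, "confusion"))
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  out <- new("EvalReport", confusion = conf,
      perClass = metricsFromConfusion(conf),
      accuracyMean = mean(acc), accuracySd = sd(acc),
      auroc = mean(vapply(res, `[[`, numeric(1), "auroc"), na.rm = TRUE),
      misclassifiedFraction = 1 - sum(diag(conf)) / sum(conf),
      foldAccuracies = acc,
      protocol = paste0("kfold(k=", k, ",", grouping, ")"))
  attr(out, "folds") <- as.integer(fold)
  out
}

#' Institution hold-out validation
#'
#' All records of the named institution form the test set; the network is
#' trained on the remaining institutions, optionally after seeded random
#' over/under-sampling of the training classes to the median class count.
#' Train and test patient sets are disjoint by construction.
#'
#' @param dataset a [StagedDataset-class].
#' @param institution label to hold out.
#' @param spec a [netSpec()].
#' @param balance `"none"` or `"resample"`.
#' @param seed resampling seed.
#' @param epochs optional override of `spec@epochs`.
#' @return an [EvalReport-class] (`accuracySd` is NA: single split).
#' @export
holdoutEval <- function(dataset, institution,
                        spec = netSpec(ncol(featureMatrix(dataset))),
                        balance = c("none", "resample"), seed = 1L,
                        epochs = NULL) {
  balance <- match.arg(balance)
  stopifnot(is(dataset, "StagedDataset"))
  te <- dataset@institutions == institution
  if (!any(te)) stop("institution '", institution, "' not present")
  X <- featureMatrix(dataset); y <- stageLabels(dataset)
  Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
  if (balance == "resample") {
    set.seed(seed)
    target <- round(median(table(ytr)))
    idx <- unlist(lapply(unique(ytr), function(cl) {
      w <- which(ytr == cl)
      if (length(w) >= target) sample(w, target)
      else c(w, sample(w, target - length(w), replace = TRUE))
    }))
    Xtr <- Xtr[idx, , drop = FALSE]; ytr <- ytr[idx]
  }
  r <- .evalSplit(Xtr, ytr, X[te, , drop = FALSE], y[te], spec, 0:4, epochs)
  new("EvalReport", confusion = r$confusion,
      perClass = metricsFromConfusion(r$confusion),
      accuracyMean = r$accuracy, accuracySd = NA_real_, auroc = r$auroc,
      misclassifiedFraction = 1 - r$accuracy,
      foldAccuracies = r$accuracy,
      protocol = paste0("holdout(", institution, ",balance=", balance, ")"))
}

#' Linear separability probe
#'
#' Multinomial logistic (softmax) regression on the normalized features
#' under the same seeded k-fold protocol as the network; a fast independent
#' check of how much of the staging signal is linearly decodable.
#'
#' @param dataset a [StagedDataset-class].
#' @param k folds.
#' @param seed shuffle seed.
#' @return mean test accuracy across folds (in [0, 1]), with per-fold
#'   accuracies as attribute `"folds"`.
#' @export
linearProbe <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(is(dataset, "StagedDataset"))
  X <- featureMatrix(dataset); y <- stageLabels(dataset)
  if (length(unique(y)) < 2L) stop("need >= 2 classes")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(X)))
  acc <- vapply(seq_len(k), function(f) {
    te <- fold == f
    nm <- normalizeFeatures(X[!te, , drop = FALSE],
                            list(X[te, , drop = FALSE]))
    df <- data.frame(y = factor(y[!te], levels = 0:4), nm$train)
    fit <- nnet::multinom(y ~ ., data = df, trace = FALSE,
                          MaxNWts = 10000L, maxit = 500L, decay = 1e-3)
    pred <- predict(fit, newdata = data.frame(nm$others[[1L]]))
    mean(as.integer(as.character(pred)) == y[te])
  }, numeric(1))
  structure(mean(acc), folds = acc)
}

#' GOLD stage from spirometry
#'
#' FEV1/FVC >= 0.70 is stage 0 (no COPD); otherwise the FEV1 percent of
#' predicted sets the stage: >= 80 mild (1), 50-80 moderate (2), 30-50
#' severe (3), < 30 very severe (4).
#'
#' @param fev1_pct FEV1 as percent of predicted (> 0).
#' @param fev1_fvc FEV1/FVC ratio in (0, 1].
#' @return integer stage(s) 0-4.
#' @examples
#' stageFromSpirometry(85, 0.65)  # 1
#' @export
stageFromSpirometry <- function(fev1_pct, fev1_fvc) {
  if (any(fev1_pct <= 0)) stop("'fev1_pct' must be positive")
  if (any(fev1_fvc <= 0 | fev1_fvc > 1)) stop("'fev1_fvc' must be in (0, 1]")
  out <- integer(length(fev1_pct))
  copd <- fev1_fvc < 0.70
  out[copd & fev1_pct >= 80] <- 1L
  out[copd & fev1_pct >= 50 & fev1_pct < 80] <- 2L
  out[copd & fev1_pct >= 30 & fev1_pct < 50] <- 3L
  out[copd & fev1_pct < 30] <- 4L
  out
}
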