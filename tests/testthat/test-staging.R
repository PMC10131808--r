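# Classifier and evaluation harness: parameter counting against layer
# enumeration, baseline builders, normalization, fold partitioning,
# confusion metrics, training behavior and the spirometry staging rule.

test_that("parameter counting equals layer-by-layer enumeration", {
  expect_equal(countParams(netSpec(2L, hidden = c(2L, 2L), n_classes = 2L)),
               18L)
  set.seed(5)
  for (i in 1:5) {
    dims <- c(sample(3:50, 1L), sample(3:40, 2L), sample(2:6, 1L))
    spec <- netSpec(dims[1L], hidden = dims[2:3], n_classes = dims[4L])
    expect_equal(countParams(spec), oracle_count_dense_stack(dims))
  }
  for (kind in c("vanilla_dnn", "lstm", "cnn")) {
    bs <- buildBaseline(kind)
    expect_equal(countParams(bs), oracle_count_baseline(bs))
  }
})

test_that("baseline builders expose the stated layers", {
  v <- buildBaseline("vanilla_dnn")
  expect_equal(v$input, 72000L)
  l <- buildBaseline("lstm")
  expect_equal(l$input, c(6000L, 12L))
  expect_equal(l$layers[[3L]]$units, 100L)       # dense layer of 100
  expect_true(attr(l, "count_discrepancy"))      # computed != published
  expect_equal(attr(l, "published_count"), 535805L)
  cn <- buildBaseline("cnn")
  expect_equal(cn$layers[[1L]]$filters, 64L)
  expect_equal(cn$layers[[4L]]$units, 32L)
})

test_that("min-max normalization is train-fitted, clipped and idempotent", {
  tr <- cbind(a = c(2, 4, 6), b = c(0, 1, 2))
  nm <- normalizeFeatures(tr, list(cbind(a = c(1, 7), b = c(0.5, 1))))
  expect_equal(unname(nm$train[, 1L]), c(0, 0.5, 1))
  expect_equal(unname(nm$others[[1L]][, 1L]), c(0, 1))  # clipped
  expect_equal(nm$clipped, 2L)
  # scaling an already normalized train table changes nothing
  nm2 <- normalizeFeatures(nm$train)
  expect_equal(nm2$train, nm$train)
  expect_warning(normalizeFeatures(cbind(c(1, 1, 1))), "constant")
})

test_that("confusion metrics match brute-force one-vs-rest counting", {
  expect_equal(unname(metricsFromConfusion(diag(10L, 5L))),
               matrix(1, 3L, 5L))
  conf <- diag(10L, 5L); conf[1L, 2L] <- 1L; conf[1L, 1L] <- 9L
  expect_equal(metricsFromConfusion(conf)["sensitivity", 1L], 0.9)
  # 3-class hand example vs enumeration oracle
  truth <- c(0, 0, 0, 1, 1, 2, 2, 2, 2)
  pred  <- c(0, 1, 0, 1, 2, 2, 2, 0, 2)
  conf3 <- table(factor(truth, 0:2), factor(pred, 0:2))
  m <- metricsFromConfusion(unclass(as.matrix(conf3)))
  o <- oracle_ovr_metrics(truth, pred, 0:2)
  expect_equal(unname(m), unname(o))
  expect_error(metricsFromConfusion(matrix(0, 5L, 5L)), "all-zero")
  # a class with no true members has undefined sensitivity (NA, not 0)
  c2 <- matrix(c(2L, 0L, 3L, 0L), 2L)
  expect_true(is.na(metricsFromConfusion(c2)["sensitivity", 2L]))
  expect_equal(metricsFromConfusion(c2)["precision", 2L], 0)
})

test_that("training is seeded-deterministic and loss decreases", {
  set.seed(30)
  K <- 5L; d <- 20L; n_per <- 30L
  mu <- matrix(rnorm(K * d, sd = 2), K, d)
  X <- do.call(rbind, lapply(1:K, function(k)
    sweep(matrix(rnorm(n_per * d, sd = 0.3), n_per, d), 2L, mu[k, ], `+`)))
  y <- rep(0:(K - 1L), each = n_per)
  nm <- normalizeFeatures(X)
  spec <- netSpec(d, epochs = 30L, seed = 4L)
  m1 <- trainFddlm(buildFddlm(spec), nm$train, y)
  m2 <- trainFddlm(buildFddlm(spec), nm$train, y)
  expect_identical(m1@weights, m2@weights)
  expect_lt(mean(tail(m1@lossHistory, 3L)), m1@lossHistory[1L])
  expect_lt(m1@lossHistory[10L], m1@lossHistory[1L])
  expect_gte(mean(predictFddlm(m1, nm$train) == y), 0.95)
  P <- predictFddlm(m1, nm$train, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
})

test_that("k-fold folds partition records and respect patient grouping", {
  set.seed(44)
  n <- 60L
  ds <- new("StagedDataset",
            features = matrix(runif(n * 10L), n, 10L),
            labels = rep(0:4, each = 12L),
            patientIds = rep(sprintf("P%02d", 1:20), each = 3L),
            institutions = rep(c("VB", "MD1", "MD2", "CP"), 15L),
            recordIds = sprintf("R%03d", 1:n), preset = "nox12",
            normalized = FALSE)
  rep1 <- kfoldEval(ds, k = 5L, spec = netSpec(10L, seed = 1L),
                    seed = 2L, epochs = 3L)
  folds <- attr(rep1, "folds")
  expect_length(folds, n)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.vector(table(folds)), rep(12L, 5L))  # 20% per test fold
  expect_equal(sum(confusionMatrix(rep1)), n)          # every record tested once
  rep2 <- kfoldEval(ds, k = 5L, grouping = "per_patient",
                    spec = netSpec(10L, seed = 1L), seed = 2L, epochs = 3L)
  f2 <- attr(rep2, "folds")
  for (p in unique(ds@patientIds))
    expect_length(unique(f2[ds@patientIds == p]), 1L)
  # determinism of the whole report under fixed seeds
  rep3 <- kfoldEval(ds, k = 5L, spec = netSpec(10L, seed = 1L),
                    seed = 2L, epochs = 3L)
  expect_equal(confusionMatrix(rep1), confusionMatrix(rep3))
  expect_equal(rep1@foldAccuracies, rep3@foldAccuracies)
})

test_that("hold-out tests exactly the held institution with disjoint patients", {
  set.seed(45)
  n <- 60L
  inst <- rep(c("VB", "MD1", "MD2", "CP"), 15L)
  pats <- paste0(inst, "_", rep(sprintf("P%02d", 1:20), each = 3L))
  ds <- new("StagedDataset",
            features = matrix(runif(n * 10L), n, 10L),
            labels = rep(0:4, each = 12L),
            patientIds = pats, institutions = inst,
            recordIds = sprintf("R%03d", 1:n), preset = "nox12",
            normalized = FALSE)
  r <- holdoutEval(ds, "MD1", spec = netSpec(10L, seed = 1L), epochs = 3L)
  expect_equal(sum(confusionMatrix(r)), sum(inst == "MD1"))
  expect_length(intersect(pats[inst == "MD1"], pats[inst != "MD1"]), 0L)
  rb <- holdoutEval(ds, "MD1", spec = netSpec(10L, seed = 1L),
                    balance = "resample", seed = 3L, epochs = 3L)
  expect_s4_class(rb, "EvalReport")
  expect_error(holdoutEval(ds, "NOPE"), "not present")
})

test_that("spirometry staging follows the GOLD thresholds", {
  expect_equal(stageFromSpirometry(90, 0.75), 0L)
  expect_equal(stageFromSpirometry(85, 0.65), 1L)
  expect_equal(stageFromSpirometry(25, 0.60), 4L)
  # boundaries: 80 is mild, just below is moderate; 50/30 likewise
  expect_equal(stageFromSpirometry(80, 0.5), 1L)
  expect_equal(stageFromSpirometry(79.9, 0.5), 2L)
  expect_equal(stageFromSpirometry(50, 0.5), 2L)
  expect_equal(stageFromSpirometry(49.9, 0.5), 3L)
  expect_equal(stageFromSpirometry(30, 0.5), 3L)
  expect_equal(stageFromSpirometry(29.9, 0.5), 4L)
  expect_equal(stageFromSpirometry(c(90, 25), c(0.75, 0.6)), c(0L, 4L))
  expect_error(stageFromSpirometry(-5, 0.5), "positive")
  expect_error(stageFromSpirometry(80, 1.5), "fev1_fvc")
})
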