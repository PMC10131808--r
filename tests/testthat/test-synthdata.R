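# Synthetic generators: exact fGn covariance, cascade oracle metadata, the
# fractional simulator against brute-force recursions, and cohort structure.

test_that("fGn matches the closed-form autocovariance", {
  H <- 0.7; n <- 4096L; nseed <- 50L
  lags <- 0:10
  emp <- matrix(0, nseed, length(lags))
  for (s in seq_len(nseed)) {
    x <- genFgn(n, H, seed = s)
    emp[s, ] <- vapply(lags, function(k)
      mean(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  }
  mc_se <- apply(emp, 2L, sd) / sqrt(nseed)
  dev <- abs(colMeans(emp) - fgnAutocov(lags, H))
  expect_true(all(dev < 3 * mc_se + 1e-12))
})

test_that("fGn limits: H = 0.5 is white, DFA slope tracks H = 0.9", {
  x <- genFgn(2^14, 0.5, seed = 1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.03)

  cfg <- mfdfaConfig(q_grid = 2)
  sl <- mean(vapply(1:5, function(s) {
    y <- genFgn(2^14, 0.9, seed = s)
    hurstExponents(hurstCurve(scalingFunction(y, cfg), cfg))[[1L]]
  }, numeric(1)))
  expect_gt(sl, 0.85)
  expect_lt(sl, 0.95)

  expect_error(genFgn(1000, 1.2, seed = 1), "hurst")
  expect_error(genFgn(1000, 0, seed = 1), "hurst")
})

test_that("binomial cascade carries its analytic exponents", {
  x <- genBinomialCascade(10, p = 0.75)
  expect_length(x, 2^10)
  hq <- attr(x, "hq")
  expect_equal(hq(2), 1 / 2 - log2(0.75^2 + 0.25^2) / 2)
  expect_gt(hq(-5), hq(5))         # strictly decreasing spectrum
  # uniform measure is monofractal with h(q) = 1
  u <- genBinomialCascade(10, p = 0.5)
  expect_equal(attr(u, "hq")(3), 1)
  expect_true(all(u == u[1L]))
  expect_error(genBinomialCascade(10, p = 1), "degenerate")
  # seeded permutation changes the layout, not the length or total mass
  xp <- genBinomialCascade(10, p = 0.75, seed = 3, permute = TRUE)
  expect_equal(sum(xp), sum(x))
  expect_false(all(xp == x))
})

test_that("fractional simulator reduces to exact known recursions", {
  sys <- make_test_system()
  n <- sys$n
  # alpha = 1: one-step memory, x[k+1] = (I + A) x[k]
  x0 <- c(1, 2, -1, 0.5)
  sp <- syntheticSpec(n, 50L, alpha = rep(1, n), A_true = 0.5 * sys$A,
                      noise_sd = 0, seed = 1, x0 = x0)
  X <- recordData(simulateFractionalSystem(sp))
  Xo <- matrix(0, n, 50L); Xo[, 1L] <- x0
  for (k in 1:49) Xo[, k + 1L] <- (diag(n) + 0.5 * sys$A) %*% Xo[, k]
  expect_equal(X, Xo, tolerance = 1e-12)

  # A = 0, B = 0, no noise: Delta^alpha x = 0, vs brute-force GL recursion
  al <- c(0.3, 0.6, 0.8, 0.5)
  sp <- syntheticSpec(n, 300L, alpha = al, A_true = matrix(0, n, n),
                      noise_sd = 0, seed = 1, x0 = c(1, -1, 2, 0.5))
  X <- recordData(simulateFractionalSystem(sp))
  Xb <- matrix(0, n, 300L); Xb[, 1L] <- c(1, -1, 2, 0.5)
  for (i in seq_len(n)) {
    psi <- glCoeffs(al[i], 300L)
    for (k in 1:299)
      Xb[i, k + 1L] <- -sum(psi[2:(k + 1L)] * Xb[i, k:1])
  }
  expect_lt(max(abs(X - Xb)), 1e-8)

  # seeded determinism
  sp <- syntheticSpec(n, 400L, alpha = sys$alpha, A_true = sys$A,
                      noise_sd = 0.1, seed = 77)
  expect_identical(recordData(simulateFractionalSystem(sp)),
                   recordData(simulateFractionalSystem(sp)))

  # divergence guard names an instability
  bad <- syntheticSpec(n, 500L, alpha = rep(0.5, n), A_true = 3 * diag(n),
                       noise_sd = 0, seed = 1, x0 = rep(1, n))
  expect_error(simulateFractionalSystem(bad), "unstable")
})

test_that("staged cohorts carry the requested structure", {
  cs <- cohortSpec(n_patients = 5L, records_per_patient = 2L,
                   n_samples = 1200L, seed = 5)
  rec <- genStagedCohort(cs)
  expect_length(rec, 10L)
  expect_equal(dim(recordData(rec[[1L]])), c(12L, 1200L))
  expect_identical(channelLabels(rec[[1L]]), channelPreset("nox12"))
  stages <- vapply(rec, copdStage, integer(1))
  expect_equal(sort(unique(stages)), 0:4)        # balanced proportions cover all stages
  expect_equal(unname(table(stages)[["0"]]), 2L) # 1 patient x 2 records per stage
  # all records of a patient share stage and institution
  pats <- vapply(rec, patientId, character(1))
  for (p in unique(pats)) {
    i <- pats == p
    expect_length(unique(stages[i]), 1L)
    expect_length(unique(vapply(rec[i], institution, character(1))), 1L)
  }
  # porti preset gives 6 channels
  cs6 <- cohortSpec(n_patients = 5L, records_per_patient = 1L,
                    channel_preset = "porti6", n_samples = 1000L, seed = 5)
  expect_equal(nrow(recordData(genStagedCohort(cs6)[[1L]])), 6L)
  # infeasible allocation errors
  expect_error(genStagedCohort(cohortSpec(n_patients = 4L, seed = 1)),
               "infeasible")
  expect_error(cohortSpec(stage_proportions = rep(0.25, 5)), "sum to 1")
})
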