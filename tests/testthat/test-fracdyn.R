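# Fractional operators and system identification: GL weights against the
# gamma-ratio oracle, fractional differencing against brute-force
# convolution, order estimation on ARFIMA fixtures, coupling recovery, the
# unknown-input alternation and the convergence study.

test_that("GL coefficients match the gamma-ratio definition", {
  expect_equal(glCoeffs(1, 3L), c(1, -1, 0, 0))
  expect_equal(glCoeffs(0, 2L), c(1, 0, 0))
  expect_equal(glCoeffs(0.5, 3L), c(1, -0.5, -0.125, -0.0625))
  for (a in c(0.3, 0.5, 0.7, -0.3, 1.4))
    expect_lt(max(abs(glCoeffs(a, 50L) - oracle_gl_gamma(a, 50L))), 1e-10)
  # binomial series of (1 - 1)^alpha: partial sums decay to 0
  expect_lt(abs(sum(glCoeffs(0.5, 512L))), 0.05)
  expect_error(glCoeffs(0.5, 0L), "J")
})

test_that("fractional differencing matches brute-force convolution", {
  expect_equal(fracDiff(rep(3, 10), 1)[-1L], rep(0, 9))
  set.seed(12)
  x <- rnorm(200)
  expect_identical(fracDiff(x, 0), x)
  psi <- glCoeffs(0.5, 64L)
  expect_lt(max(abs(fracDiff(x, 0.5, 64L) - oracle_conv(x, psi))), 1e-12)
  # inverse-operator identity away from the boundary
  y <- fracDiff(fracDiff(x, 0.5), -0.5)
  expect_lt(max(abs(y[50:150] - x[50:150])), 1e-8)
})

test_that("long-memory order estimation recovers ARFIMA fixtures", {
  expect_lt(abs(as.numeric(estimateAlpha(genFgn(2^14, 0.5, seed = 1)))), 0.1)
  # ARFIMA(0, d, 0) with d = 0.3 by GL inversion of white noise
  for (m in c("dfa", "gph")) {
    est <- mean(vapply(1:5, function(s) {
      set.seed(s)
      x <- fracDiff(rnorm(4096), -0.3)
      as.numeric(estimateAlpha(x, method = m))
    }, numeric(1)))
    expect_gt(est, 0.2); expect_lt(est, 0.4)
  }
  # scale invariance
  set.seed(2); x <- fracDiff(rnorm(4096), -0.3)
  expect_equal(as.numeric(estimateAlpha(x)),
               as.numeric(estimateAlpha(100 * x)), tolerance = 1e-10)
  expect_warning(estimateAlpha(rnorm(512)), "wide uncertainty")
})

test_that("coupling least squares recovers the generating matrix", {
  sys <- make_test_system()
  sp <- syntheticSpec(sys$n, 2000L, alpha = sys$alpha, A_true = sys$A,
                      noise_sd = 0, seed = 3, x0 = rnorm(sys$n))
  X <- recordData(simulateFractionalSystem(sp))
  Ah <- fitCoupling(X, sys$alpha)
  expect_lt(sqrt(sum((Ah - sys$A)^2)) / sqrt(sum(sys$A^2)), 0.01)

  # permutation equivariance: reordering channels permutes A consistently
  perm <- c(3L, 1L, 4L, 2L)
  Ap <- fitCoupling(X[perm, ], sys$alpha[perm])
  expect_equal(Ap, Ah[perm, perm], tolerance = 1e-8,
               ignore_attr = TRUE)

  # all-zero record falls back to ridge and returns A = 0
  Z <- matrix(0, 4L, 100L)
  expect_message(A0 <- fitCoupling(Z, rep(0.4, 4L)), "ridge")
  expect_equal(unname(A0), matrix(0, 4L, 4L), ignore_attr = TRUE)
  expect_gt(attr(A0, "ridge_lambda"), 0)
})

test_that("unknown-input alternation honors its contract and helps", {
  sys <- make_test_system()
  sp <- syntheticSpec(sys$n, 1500L, alpha = sys$alpha, A_true = sys$A,
                      noise_sd = 0.1, seed = 4)
  X <- recordData(simulateFractionalSystem(sp))
  m0 <- fitUnknownInputs(X, sys$alpha, 0L)
  expect_identical(unname(couplingMatrix(m0)),
                   unname(fitCoupling(X, sys$alpha)))
  expect_equal(m0@p, 0L)

  B <- matrix(c(1, -0.5, 0.3, 0.8), sys$n, 1L)
  err <- function(M) sqrt(sum((couplingMatrix(M) - sys$A)^2))
  e0 <- e1 <- numeric(4)
  for (s in 1:4) {
    spB <- syntheticSpec(sys$n, 2000L, alpha = sys$alpha, A_true = sys$A,
                         B_true = B, u_kind = "sparse_impulses",
                         noise_sd = 0.05, seed = s)
    Xb <- recordData(simulateFractionalSystem(spB))
    f0 <- fitUnknownInputs(Xb, sys$alpha, 0L)
    f1 <- fitUnknownInputs(Xb, sys$alpha, 1L)
    expect_true(all(diff(f1@residualHistory) <= 1e-9))
    e0[s] <- err(f0); e1[s] <- err(f1)
  }
  expect_lt(mean(e1), mean(e0))  # planted rank-1 input: A-hat improves
  expect_error(fitUnknownInputs(X, sys$alpha, 4L), "strictly smaller")
})

test_that("feature extraction is deterministic with the preset widths", {
  rec <- fixture_small_record()
  f1 <- extractFeature(rec, "nox12")
  f2 <- extractFeature(rec, "nox12")
  expect_length(f1, 144L)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_length(attr(f1, "alpha"), 12L)

  set.seed(10)
  A6 <- -0.5 * diag(6) + matrix(rnorm(36, sd = 0.08), 6L, 6L)
  rec6 <- simulateFractionalSystem(
    syntheticSpec(6L, 1200L, alpha = rep(0.4, 6L), A_true = A6, seed = 2),
    channels = channelPreset("porti6"))
  expect_length(extractFeature(rec6, "porti6"), 36L)
  expect_error(extractFeature(rec6, "nox12"), "channel mismatch")
})

test_that("coupling estimates converge with window length", {
  sys <- make_test_system()
  devs <- sapply(1:5, function(s) {
    sp <- syntheticSpec(sys$n, 4096L, alpha = sys$alpha, A_true = sys$A,
                        noise_sd = 0.1, seed = 100 + s)
    rec <- simulateFractionalSystem(sp)
    cv <- convergenceStudy(rec, c(500L, 2000L, 4096L), alpha = sys$alpha)
    expect_true(all(cv$rel_deviation >= 0))
    expect_equal(cv$rel_deviation[cv$window == 4096L], 0, tolerance = 1e-10)
    cv$rel_deviation
  })
  expect_lt(mean(devs[2L, ]), mean(devs[1L, ]))  # longer window, closer A
  rec <- simulateFractionalSystem(
    syntheticSpec(4L, 256L, alpha = rep(0.4, 4L),
                  A_true = make_test_system()$A, seed = 1))
  expect_message(convergenceStudy(rec, c(3L, 256L), alpha = rep(0.4, 4L)),
                 "skipped")
})
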