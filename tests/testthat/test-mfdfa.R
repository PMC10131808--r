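# MF-DFA: profile, window fluctuations against hand least squares, scaling
# function vs classical DFA, Hurst curves on analytic fixtures, group bands,
# Wasserstein distances and the multifractality report.

test_that("cumulative profile telescopes to zero", {
  expect_equal(fluctuationProfile(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(fluctuationProfile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  set.seed(3)
  x <- rnorm(257)
  expect_equal(tail(fluctuationProfile(x), 1L), 0, tolerance = 1e-10)
  expect_error(fluctuationProfile(numeric(0)), "empty")
})

test_that("window fluctuation equals a hand least-squares fit", {
  # perfectly linear window detrends to zero
  Y <- 2 * (1:10) + 3
  expect_equal(windowFluctuation(Y, 1L, 10L), 0, tolerance = 1e-12)
  # Y = (0, 1, 0): residuals from the OLS line fitted by hand
  Yw <- c(0, 1, 0)
  tt <- 1:3
  r <- resid(lm(Yw ~ tt))
  expect_equal(windowFluctuation(Yw, 1L, 3L), sqrt(mean(r^2)))
  # homogeneity: doubling the profile doubles F
  set.seed(4); Y2 <- cumsum(rnorm(64))
  expect_equal(windowFluctuation(2 * Y2, 2L, 16L),
               2 * windowFluctuation(Y2, 2L, 16L))
  expect_error(windowFluctuation(Y2, 1L, 2L), "ill-posed")
})

test_that("q = 2 column of the scaling function is classical DFA", {
  set.seed(8)
  x <- rnorm(2048)
  scales <- c(16L, 32L, 64L, 128L)
  surf <- scalingFunction(x, mfdfaConfig(q_grid = c(-2, 2), scales = scales))
  for (j in seq_along(scales))
    expect_equal(surf@S[2L, j], oracle_dfa_f2(x, scales[j]),
                 tolerance = 1e-10)
})

test_that("focus point is the full-length window fluctuation, independent of q", {
  set.seed(15)
  x <- as.numeric(genBinomialCascade(11, 0.7))
  surf <- scalingFunction(x, mfdfaConfig())
  Y <- fluctuationProfile(x)
  expect_equal(focusPoint(surf), windowFluctuation(Y, 1L, length(x)),
               tolerance = 1e-12)
  # homogeneity of the whole surface; H(q) invariant under scaling of x
  surf5 <- scalingFunction(5 * x, mfdfaConfig())
  expect_equal(surf5@S, 5 * surf@S, tolerance = 1e-10)
  c1 <- hurstCurve(surf, mfdfaConfig())
  c5 <- hurstCurve(surf5, mfdfaConfig())
  expect_equal(c1@H, c5@H, tolerance = 1e-10)
})

test_that("Hurst curves recover analytic exponents in both fit modes", {
  x <- genBinomialCascade(14, 0.75)
  hq <- attr(x, "hq")
  for (mode in c("per_q_ols", "focus_regression")) {
    cfg <- mfdfaConfig(fit_mode = mode)
    crv <- hurstCurve(scalingFunction(x, cfg), cfg)
    expect_true(all(abs(crv@H - hq(crv@qGrid)) < 0.1),
                label = paste("cascade H(q) within 0.1,", mode))
    expect_true(all(diff(crv@H) < 0))   # non-increasing in q
  }
  # monofractal white noise: flat curve at 0.5
  cfg <- mfdfaConfig()
  crv <- hurstCurve(scalingFunction(genFgn(2^14, 0.5, seed = 2), cfg), cfg)
  expect_true(all(abs(crv@H - 0.5) < 0.05))
})

test_that("group band covers the generating exponent", {
  # The 95% band is an interval on the mean H(q); on finite fGn the MF-DFA
  # estimator carries a small finite-size bias at extreme q, so coverage is
  # assessed against an independently replicated finite-sample mean
  # (simulation oracle), and against the generating H = 0.6 at the central
  # moments where the bias is negligible.
  cfg <- mfdfaConfig(q_grid = setdiff(-5:5, 0))
  curves <- lapply(1:50, function(s)
    hurstCurve(scalingFunction(genFgn(2^12, 0.6, seed = s), cfg), cfg))
  band <- groupHurstBand(curves)
  expect_equal(band@nCurves, 50L)
  ref <- rowMeans(vapply(201:320, function(s)
    hurstCurve(scalingFunction(genFgn(2^12, 0.6, seed = s), cfg), cfg)@H,
    numeric(length(cfg$q_grid))))
  covered <- band@ci95[1L, ] <= ref & ref <= band@ci95[2L, ]
  expect_gte(mean(covered), 0.9)
  central <- abs(band@qGrid) <= 1
  expect_true(all(band@ci95[1L, central] <= 0.6 &
                  0.6 <= band@ci95[2L, central]))
  expect_true(all(band@ci95[1L, ] <= band@H & band@H <= band@ci95[2L, ]))
  # identical curves give a zero-width band
  same <- groupHurstBand(list(curves[[1L]], curves[[1L]]))
  expect_equal(same@ci95[1L, ], same@ci95[2L, ], tolerance = 1e-12)
  expect_error(groupHurstBand(curves[1L]), ">= 2")
})

test_that("Wasserstein distance has the W1 identities", {
  cfg <- mfdfaConfig()
  crv <- hurstCurve(scalingFunction(genFgn(2^12, 0.7, seed = 1), cfg), cfg)
  expect_equal(hqWasserstein(crv, crv), 0)
  shifted <- crv; shifted@H <- crv@H + 0.3
  expect_equal(hqWasserstein(crv, shifted), 0.3, tolerance = 1e-12)
  expect_equal(hqWasserstein(c(0, 1), c(1, 2)), 1.0)
  bad <- crv; bad@H[1L] <- NA_real_
  expect_error(hqWasserstein(crv, bad), "non-finite")
})

test_that("multifractality report separates cascade from fGn", {
  rep_mf <- multifractalityReport(as.numeric(genBinomialCascade(14, 0.75)))
  expect_gt(rep_mf$delta_h, 0.2)
  expect_true(rep_mf$multifractal)
  expect_lt(rep_mf$focus_deviation, 0.5)
  rep_mono <- multifractalityReport(genFgn(2^14, 0.6, seed = 6))
  expect_lt(rep_mono$delta_h, 0.1)
  expect_false(rep_mono$multifractal)
  expect_true(all(is.finite(rep_mono$r_squared)))
  expect_true(all(is.finite(unlist(rep_mono[c("focus_deviation", "delta_h")]))))
})
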