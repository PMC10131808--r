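# Focus-based multifractal detrended fluctuation analysis: cumulative
# profile, windowed detrended fluctuations, moment-wise scaling functions
# with a focus point at the full signal length, generalized Hurst exponents,
# group confidence bands and Wasserstein comparison of H(q) curves.

#' MF-DFA configuration
#'
#' @param q_grid moment orders; 0 is excluded by default (when present it is
#'   handled by the logarithmic-average limit).
#' @param scales window lengths s, strictly increasing; `NULL` picks
#'   `n_scales` log-spaced scales from `min_scale` to L/4 at analysis time.
#' @param detrend_order polynomial detrending order (1 = local straight-line
#'   fit).
#' @param fit_mode `"per_q_ols"` fits each log S(q, s) ~ log s line
#'   independently; `"focus_regression"` constrains every line to pass
#'   through the measured focus at (log L, log S(q, L)).
#' @param n_scales,min_scale used when `scales` is `NULL`.
#' @return list of class `"MfdfaConfig"`.
#' @export
mfdfaConfig <- function(q_grid = c(-5, -3, -1, 1, 3, 5), scales = NULL,
                        detrend_order = 1L,
                        fit_mode = c("per_q_ols", "focus_regression"),
                        n_scales = 16L, min_scale = 16L) {
  fit_mode <- match.arg(fit_mode)
  if (!is.null(scales)) {
    if (is.unsorted(scales, strictly = TRUE))
      stop("'scales' must be strictly increasing")
    if (min(scales) < detrend_order + 2)
      stop("minimum scale must be >= detrend_order + 2")
  }
  if (min_scale < detrend_order + 2)
    stop("'min_scale' must be >= detrend_order + 2")
  structure(list(q_grid = q_grid, scales = scales,
                 detrend_order = as.integer(detrend_order),
                 fit_mode = fit_mode, n_scales = as.integer(n_scales),
                 min_scale = as.integer(min_scale)),
            class = "MfdfaConfig")
}

.defaultScales <- function(L, cfg) {
  smax <- floor(L / 4)
  if (smax < cfg$min_scale) stop("series too short for the requested scales")
  unique(round(exp(seq(log(cfg$min_scale), log(smax),
                       length.out = cfg$n_scales))))
}

#' Cumulative profile of a series
#'
#' Y(t) = sum_{i <= t} (X(i) - mean(X)); the final value is 0 up to rounding.
#'
#' @param x numeric series (length >= 2; a constant series gives zeros).
#' @return numeric profile of the same length.
#' @export
fluctuationProfile <- function(x) {
  if (length(x) < 1L) stop("empty series")
  cumsum(x - mean(x))
}

#' Detrended fluctuation of one window
#'
#' Root-mean-square deviation of the profile from its least-squares
#' polynomial trend over window v of scale s:
#' F(v, s) = sqrt(mean((Y[(v-1)s + i] - y_v(i))^2)).
#'
#' @param Y profile series (see [fluctuationProfile()]).
#' @param v 1-based window index.
#' @param s window length.
#' @param detrend_order polynomial order of the local trend.
#' @return nonnegative fluctuation value.
#' @export
windowFluctuation <- function(Y, v, s, detrend_order = 1L) {
  if (s < detrend_order + 2) stop("ill-posed fit: scale must be >= detrend_order + 2")
  idx <- ((v - 1L) * s + 1L):(v * s)
  if (max(idx) > length(Y)) stop("window does not fit in the profile")
  yw <- Y[idx]
  t <- seq_len(s)
  fit <- lm.fit(outer(t, 0:detrend_order, `^`), yw)
  sqrt(mean(fit$residuals^2))
}

# All window fluctuations at one scale, vectorized: reshape the profile into
# an s x Ns matrix and project out the polynomial trend per column.
.fluctuationsAtScale <- function(Y, s, detrend_order) {
  Ns <- length(Y) %/% s
  W <- matrix(Y[seq_len(Ns * s)], nrow = s)
  X <- outer(seq_len(s), 0:detrend_order, `^`)
  Q <- qr.Q(qr(X))
  R <- W - Q %*% crossprod(Q, W)
  sqrt(colMeans(R^2))
}

# Moment-wise aggregation {mean_v F^q}^(1/q); q = 0 via the log-average
# limit; F = 0 windows dropped for q < 0 (counted by the caller).
.momentAggregate <- function(Fv, q) {
  if (q == 0) return(exp(mean(log(Fv[Fv > 0]))))
  if (q < 0) Fv <- Fv[Fv > 0]
  (mean(Fv^q))^(1 / q)
}

#' Moment-wise scaling function and focus point
#'
#' Computes S_F(q, s) = {(1/N_s) sum_v F(v, s)^q}^(1/q) over the configured
#' q grid and scales, with non-overlapping windows from the series start, and
#' the focus estimate S(q, L): the single globally detrended window at the
#' full length L, which is independent of q by construction. Setting q = 2
#' recovers the classical DFA fluctuation function.
#'
#' @param x numeric series; length must be >= 4x the maximum scale.
#' @param cfg an [mfdfaConfig()].
#' @return a [ScalingSurface-class].
#' @export
scalingFunction <- function(x, cfg = mfdfaConfig()) {
  L <- length(x)
  scales <- if (is.null(cfg$scales)) .defaultScales(L, cfg) else cfg$scales
  if (L < 4 * max(scales)) stop("series length must be >= 4x the maximum scale")
  Y <- fluctuationProfile(x)
  q <- cfg$q_grid
  S <- matrix(NA_real_, length(q), length(scales))
  nW <- integer(length(scales))
  dropped <- 0L
  for (j in seq_along(scales)) {
    Fv <- .fluctuationsAtScale(Y, scales[j], cfg$detrend_order)
    nW[j] <- length(Fv)
    if (any(Fv == 0) && any(q <= 0)) dropped <- dropped + sum(Fv == 0)
    S[, j] <- vapply(q, function(qq) .momentAggregate(Fv, qq), numeric(1))
  }
  focus <- .fluctuationsAtScale(Y, L, cfg$detrend_order)[1L]
  new("ScalingSurface", S = S, qGrid = q, scales = as.numeric(scales),
      L = as.integer(L), focus = focus, nWindows = nW,
      droppedWindows = dropped)
}

#' Generalized Hurst exponents from a scaling surface
#'
#' In `"per_q_ols"` mode H(q) is the OLS slope of log S(q, s) on log s; in
#' `"focus_regression"` mode every fitted line is constrained to pass through
#' the focus (log L, log S(q, L)), so the slopes are estimated by regression
#' through that common point. Regression standard errors and 95% intervals
#' are reported per q; scales with non-finite S are excluded (counted in the
#' attribute `"excluded"`).
#'
#' @param surface a [ScalingSurface-class].
#' @param cfg the [mfdfaConfig()] (controls `fit_mode`).
#' @return a [HurstCurve-class].
#' @export
hurstCurve <- function(surface, cfg = mfdfaConfig()) {
  stopifnot(is(surface, "ScalingSurface"))
  if (length(surface@scales) < 4) stop("need >= 4 scales to fit H(q)")
  q <- surface@qGrid
  ls <- log(surface@scales)
  H <- se <- numeric(length(q))
  excluded <- 0L
  for (i in seq_along(q)) {
    lS <- log(surface@S[i, ])
    ok <- is.finite(lS)
    excluded <- excluded + sum(!ok)
    if (cfg$fit_mode == "per_q_ols") {
      fit <- lm(lS[ok] ~ ls[ok])
      H[i] <- coef(fit)[2L]
      se[i] <- summary(fit)$coefficients[2L, 2L]
    } else {
      # slope through the fixed point (log L, log focus)
      dx <- ls[ok] - log(surface@L)
      dy <- lS[ok] - log(surface@focus)
      H[i] <- sum(dx * dy) / sum(dx * dx)
      res <- dy - H[i] * dx
      dfree <- max(sum(ok) - 1L, 1L)
      se[i] <- sqrt(sum(res^2) / dfree / sum(dx * dx))
    }
  }
  ci <- rbind(H - 1.96 * se, H + 1.96 * se)
  out <- new("HurstCurve", qGrid = q, H = H, stderr = se, ci95 = ci,
             fitMode = cfg$fit_mode, nCurves = 1L)
  attr(out, "excluded") <- excluded
  if (excluded > 0) warning(excluded, " non-finite scaling values excluded from the fit")
  out
}

#' Group mean and confidence band of H(q) curves
#'
#' Per-q mean of H(q) across signals with a t-based 95% interval on the mean.
#'
#' @param curves list of >= 2 [HurstCurve-class] objects on an identical q
#'   grid.
#' @return a [HurstCurve-class] whose `ci95` is the group band.
#' @export
groupHurstBand <- function(curves) {
  if (length(curves) < 2L) stop("need >= 2 curves")
  q <- curves[[1L]]@qGrid
  for (cv in curves)
    if (!identical(cv@qGrid, q)) stop("curves must share the same q grid")
  Hmat <- do.call(rbind, lapply(curves, function(cv) cv@H))
  m <- colMeans(Hmat)
  s <- apply(Hmat, 2L, sd) / sqrt(nrow(Hmat))
  tq <- qt(0.975, df = nrow(Hmat) - 1L)
  new("HurstCurve", qGrid = q, H = m, stderr = s,
      ci95 = rbind(m - tq * s, m + tq * s), fitMode = curves[[1L]]@fitMode,
      nCurves = length(curves))
}

#' First Wasserstein distance between two H(q) curves
#'
#' Treats the H(q) values of each curve as equally weighted one-dimensional
#' samples and returns the optimal-transport (W1) distance between the two
#' empirical distributions: the mean absolute difference of matched order
#' statistics (for equal sample sizes), i.e. the area between the empirical
#' quantile functions. A pointwise translation of a curve by c moves it by
#' exactly |c|.
#'
#' @param c1,c2 [HurstCurve-class] objects on the same q grid, or plain
#'   numeric sample vectors of equal meaning.
#' @return nonnegative distance.
#' @export
hqWasserstein <- function(c1, c2) {
  v1 <- if (is(c1, "HurstCurve")) c1@H else as.numeric(c1)
  v2 <- if (is(c2, "HurstCurve")) c2@H else as.numeric(c2)
  if (is(c1, "HurstCurve") && is(c2, "HurstCurve") &&
      !identical(c1@qGrid, c2@qGrid)) stop("curves must share the same q grid")
  if (any(!is.finite(v1)) || any(!is.finite(v2)))
    stop("non-finite H values")
  # W1 between empirical distributions via the quantile-function integral
  p <- sort(unique(c(seq_along(v1) / length(v1), seq_along(v2) / length(v2))))
  w <- diff(c(0, p))
  qf <- function(v, pr) sort(v)[pmin(length(v), ceiling(pr * length(v)))]
  sum(w * abs(qf(v1, p) - qf(v2, p)))
}

#' Multifractality summary of a series
#'
#' Runs the full MF-DFA and reports (a) the focus-convergence deviation: the
#' RMS gap, in log space, between the per-q fitted lines extrapolated to
#' s = L and the measured focus; (b) the H(q) spread Delta H = H(min q) -
#' H(max q); (c) the per-q fit R^2. The series is flagged multifractal-like
#' when Delta H exceeds `delta_h_threshold` and the fits are good.
#'
#' @param x numeric series.
#' @param cfg an [mfdfaConfig()].
#' @param delta_h_threshold spread above which the signal is flagged
#'   multifractal-like (default 0.15).
#' @param min_r2 minimum mean per-q R^2 for the flag.
#' @return list with `surface`, `curve`, `focus_deviation`, `delta_h`,
#'   `r_squared`, `multifractal`.
#' @export
multifractalityReport <- function(x, cfg = mfdfaConfig(),
                                  delta_h_threshold = 0.15, min_r2 = 0.9) {
  surf <- scalingFunction(x, cfg)
  crv <- hurstCurve(surf, cfg)
  ls <- log(surf@scales)
  r2 <- pred_at_L <- numeric(length(surf@qGrid))
  for (i in seq_along(surf@qGrid)) {
    lS <- log(surf@S[i, ])
    if (cfg$fit_mode == "per_q_ols") {
      fit <- lm(lS ~ ls)
      r2[i] <- summary(fit)$r.squared
      pred_at_L[i] <- coef(fit)[1L] + coef(fit)[2L] * log(surf@L)
    } else {
      pred_at_L[i] <- log(surf@focus)
      res <- (lS - log(surf@focus)) - crv@H[i] * (ls - log(surf@L))
      r2[i] <- 1 - sum(res^2) / sum((lS - mean(lS))^2)
    }
  }
  dh <- crv@H[which.min(surf@qGrid)] - crv@H[which.max(surf@qGrid)]
  fdev <- sqrt(mean((pred_at_L - log(surf@focus))^2))
  list(surface = surf, curve = crv, focus_deviation = fdev, delta_h = dh,
       r_squared = r2,
       multifractal = (dh > delta_h_threshold) && mean(r2) >= min_r2)
}
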