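# Discrete fractional-order multivariate modeling: Grünwald-Letnikov
# coefficients, fractional differencing, long-memory order estimation,
# coupling-matrix least squares, alternating estimation with unknown inputs,
# and window-length convergence analysis.

#' Grünwald-Letnikov coefficients
#'
#' psi(alpha, j) = Gamma(j - alpha) / (Gamma(-alpha) Gamma(j + 1)) for
#' j = 0..J, computed by the numerically stable recursion
#' psi(alpha, j) = psi(alpha, j - 1) (j - 1 - alpha) / j with
#' psi(alpha, 0) = 1. For alpha = 1 the weights are (1, -1, 0, ...): the
#' first-difference operator; alpha = 0 is the identity.
#'
#' @param alpha real fractional order.
#' @param J truncation length (>= 1).
#' @return numeric vector of length J + 1 (indices j = 0..J).
#' @examples
#' glCoeffs(0.5, 3)   # 1, -0.5, -0.125, -0.0625
#' @export
glCoeffs <- function(alpha, J) {
  if (J < 1) stop("'J' must be >= 1")
  if (!is.finite(alpha)) stop("'alpha' must be finite")
  .gl_coeffs_cpp(alpha, as.integer(J))
}

#' Truncated fractional difference of a series
#'
#' (Delta^alpha x)[k] = sum_{j=0}^{min(k, J)} psi(alpha, j) x[k - j], with no
#' pre-sample history (the first output equals x[1]). alpha = 0 returns the
#' series unchanged; alpha = 1 returns first differences.
#'
#' @param x numeric series.
#' @param alpha fractional order.
#' @param J memory truncation; defaults to the full history.
#' @return numeric series of the same length.
#' @export
fracDiff <- function(x, alpha, J = length(x)) {
  if (length(x) < 1L) stop("empty series")
  .frac_diff_cpp(as.numeric(x), glCoeffs(alpha, max(1L, as.integer(J))))
}

# DFA(1) Hurst estimate: slope of log F(2, s) on log s.
.dfaHurst <- function(x, n_scales = 12L) {
  cfg <- mfdfaConfig(q_grid = 2, n_scales = n_scales)
  surf <- scalingFunction(x, cfg)
  unname(coef(lm(log(surf@S[1L, ]) ~ log(surf@scales)))[2L])
}

#' Estimate the long-memory fractional order of a series
#'
#' Default method maps the DFA(1) Hurst estimate H to alpha = H - 1/2 (the
#' ARFIMA correspondence d = H - 1/2). The alternative `"gph"` is the
#' log-periodogram (Geweke-Porter-Hudak) regression of log I(w) on
#' -log(4 sin^2(w/2)) over the lowest floor(sqrt(n)) frequencies. Both are
#' clipped to `interval`. Series shorter than 1024 samples trigger a warning
#' and carry the attribute `wide_uncertainty = TRUE`.
#'
#' @param x numeric series.
#' @param method `"dfa"` or `"gph"`.
#' @param interval admissible range the estimate is clipped to.
#' @return scalar alpha estimate with attribute `"method"`.
#' @export
estimateAlpha <- function(x, method = c("dfa", "gph"),
                          interval = c(-0.5, 1.5)) {
  method <- match.arg(method)
  short <- length(x) < 1024L
  if (short) warning("series shorter than 1024 samples: alpha estimate has wide uncertainty")
  a <- if (method == "dfa") {
    .dfaHurst(x) - 0.5
  } else {
    n <- length(x)
    m <- floor(sqrt(n))
    w <- 2 * pi * seq_len(m) / n
    I <- Mod(fft(x - mean(x))[seq_len(m) + 1L])^2 / (2 * pi * n)
    unname(coef(lm(log(I) ~ I(-log(4 * sin(w / 2)^2))))[2L])
  }
  a <- min(max(a, interval[1L]), interval[2L])
  attr(a, "method") <- method
  if (short) attr(a, "wide_uncertainty") <- TRUE
  a
}

# Fractionally difference the rows of X and set up the regression
# z[k+1] ~ x[k]; returns list(Z1 = n x (T-1) responses, X0 = n x (T-1)
# regressor states).
.glRegression <- function(X, alpha, J) {
  T <- ncol(X)
  Z <- .frac_diff_rows_cpp(X, alpha, as.integer(J))
  list(Z1 = Z[, 2:T, drop = FALSE], X0 = X[, 1:(T - 1L), drop = FALSE])
}

# Row-wise least squares of responses Z1 on states X0 with a ridge fallback
# for rank-deficient regressors.
.solveCoupling <- function(Z1, X0) {
  G <- tcrossprod(X0)                       # n x n Gram matrix
  Cz <- tcrossprod(Z1, X0)                  # n x n cross moments
  lambda <- 0
  if (!all(is.finite(G)) || rcond(G) < 1e-12) {
    lambda <- 1e-8 * max(mean(diag(G)), 1)
    message("rank-deficient regressor matrix: ridge fallback with lambda = ",
            signif(lambda, 3))
    G <- G + lambda * diag(nrow(G))
  }
  A <- t(solve(G, t(Cz)))
  attr(A, "ridge_lambda") <- lambda
  A
}

#' Least-squares fit of the coupling matrix
#'
#' Forms the fractional differences z_i[k+1] = (Delta^alpha_i x_i)[k+1] and
#' solves min_A sum_k || z[k+1] - A x[k] ||^2 row-wise by ordinary least
#' squares. A rank-deficient regressor matrix triggers a ridge fallback with
#' a tiny logged regularization.
#'
#' @param X n x T multichannel matrix (rows = channels), T > n + 1.
#' @param alpha per-channel fractional orders (length n).
#' @param J Grünwald-Letnikov memory truncation (default: full history).
#' @return n x n coupling matrix (attribute `"ridge_lambda"` records the
#'   regularization used, 0 for plain OLS).
#' @export
fitCoupling <- function(X, alpha, J = ncol(X)) {
  n <- nrow(X)
  if (ncol(X) <= n + 1L) stop("need T > n + 1 samples")
  if (length(alpha) != n) stop("'alpha' must have one entry per channel")
  r <- .glRegression(X, alpha, J)
  .solveCoupling(r$Z1, r$X0)
}

#' Alternating estimation with unknown low-dimensional inputs
#'
#' Fits the fractional model Delta^alpha x[k+1] = A x[k] + B u[k] with an
#' unobserved p-dimensional input (p < n) by alternating estimation:
#' (i) given the input term fixed, update A by row-wise least squares on
#' z[k+1] - B u[k]; (ii) given A, re-estimate the input term as the top-p
#' SVD of the residual sequence restricted to its highest-energy time
#' columns (fraction `support_frac`), reflecting that unobserved stimuli are
#' intermittent and low-dimensional. An unrestricted rank-p factorization of
#' the full residual is a fixed point of the alternation (the least-squares
#' residual is orthogonal to the regressor rows), so the column restriction
#' is what lets the input term feed back into A. A descent guard keeps the
#' previous input term whenever the candidate does not lower the objective,
#' so the recorded residual norms are non-increasing. `p = 0` reduces
#' exactly to [fitCoupling()].
#'
#' @param X n x T multichannel matrix.
#' @param alpha per-channel fractional orders.
#' @param p input dimension, 0 <= p < n.
#' @param max_iter,tol iteration cap and relative-residual-change tolerance.
#' @param J memory truncation (default full history).
#' @param support_frac fraction of time columns the input term may occupy.
#' @return a [FractionalModel-class]; `converged` is FALSE (with a warning)
#'   if `max_iter` was exhausted.
#' @export
fitUnknownInputs <- function(X, alpha, p, max_iter = 50L, tol = 1e-8,
                             J = ncol(X), support_frac = 0.05) {
  n <- nrow(X)
  if (p >= n) stop("input dimension p must be strictly smaller than n")
  r <- .glRegression(X, alpha, J)
  if (p == 0L) {
    A <- .solveCoupling(r$Z1, r$X0)
    res <- sqrt(sum((r$Z1 - A %*% r$X0)^2))
    m <- new("FractionalModel", alpha = alpha, A = A,
             B = matrix(0, n, 0L), U = matrix(0, 0L, ncol(r$X0)), p = 0L,
             residualHistory = res, memoryJ = as.integer(J),
             converged = TRUE)
    m@C <- diag(n)
    return(m)
  }
  Tm1 <- ncol(r$X0)
  mcols <- max(p, ceiling(support_frac * Tm1))
  BU <- matrix(0, n, Tm1)
  B <- matrix(0, n, p); U <- matrix(0, p, Tm1)
  hist <- numeric(0)
  converged <- FALSE
  A <- NULL
  for (it in seq_len(max_iter)) {
    A <- .solveCoupling(r$Z1 - BU, r$X0)
    Rfull <- r$Z1 - A %*% r$X0
    # candidate input term: top-p factors on the highest-energy columns
    cn <- colSums(Rfull^2)
    S <- order(cn, decreasing = TRUE)[seq_len(mcols)]
    sv <- svd(Rfull[, S, drop = FALSE], nu = p, nv = p)
    Bc <- sv$u
    Uc <- matrix(0, p, Tm1)
    Uc[, S] <- diag(sv$d[seq_len(p)], p, p) %*% t(sv$v)
    cand <- Bc %*% Uc
    if (sum((Rfull - cand)^2) <= sum((Rfull - BU)^2)) {
      B <- Bc; U <- Uc; BU <- cand
    }
    res <- sqrt(sum((Rfull - BU)^2))
    hist <- c(hist, res)
    if (it > 1L &&
        abs(hist[it - 1L] - res) <= tol * max(hist[it - 1L], 1e-300)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("alternating estimation did not converge in ",
                          max_iter, " iterations")
  m <- new("FractionalModel", alpha = alpha, A = A, B = B, U = U,
           p = as.integer(p), residualHistory = hist,
           memoryJ = as.integer(J), converged = converged)
  m@C <- diag(n)
  m
}

#' Extract the flattened coupling-matrix feature vector of a record
#'
#' Estimates the per-channel fractional orders, fits the coupling matrix (via
#' [fitCoupling()] when `p = 0`, else [fitUnknownInputs()]) and flattens A
#' row-major into the feature vector: 144 values for the 12-channel preset,
#' 36 for the 6-channel preset. Normalization to [0, 1] is a dataset-level
#' step (see [normalizeFeatures()]), not applied here.
#'
#' @param record a [MultichannelRecord-class].
#' @param preset expected channel preset (`"nox12"` or `"porti6"`).
#' @param J memory truncation (default full record length).
#' @param p unknown-input dimension (default 0).
#' @param alpha optional known fractional orders; estimated per channel with
#'   [estimateAlpha()] when `NULL`.
#' @param alpha_method estimation method passed to [estimateAlpha()].
#' @return numeric feature vector of class `"FeatureVector"` with attributes
#'   `alpha`, `source_record`, `normalized = FALSE`.
#' @export
extractFeature <- function(record, preset = c("nox12", "porti6"),
                           J = ncol(recordData(record)), p = 0L,
                           alpha = NULL, alpha_method = "dfa") {
  preset <- match.arg(preset)
  expected <- channelPreset(preset)
  if (!identical(channelLabels(record), expected))
    stop("channel mismatch for preset '", preset, "': expected [",
         paste(expected, collapse = ", "), "], got [",
         paste(channelLabels(record), collapse = ", "), "]")
  X <- recordData(record)
  if (is.null(alpha))
    alpha <- vapply(seq_len(nrow(X)),
                    function(i) as.numeric(estimateAlpha(X[i, ],
                                                         method = alpha_method)),
                    numeric(1))
  A <- if (p == 0L) fitCoupling(X, alpha, J)
       else couplingMatrix(fitUnknownInputs(X, alpha, p, J = J))
  v <- as.vector(t(A))                      # row-major flattening
  structure(v, class = "FeatureVector", alpha = alpha,
            source_record = record@recordId, normalized = FALSE)
}

#' Coupling-matrix convergence over nested windows
#'
#' Fits the coupling matrix on nested record prefixes and reports the
#' relative Frobenius deviation || A_w - A_full ||_F / || A_full ||_F per
#' window length. On simulated data the deviation shrinks with the window, a
#' practical signal-length sufficiency check.
#'
#' @param record a [MultichannelRecord-class].
#' @param window_lengths prefix lengths to evaluate; windows shorter than
#'   n + 2 are skipped with a message.
#' @param alpha optional known fractional orders (estimated when `NULL`).
#' @return data.frame with columns `window` and `rel_deviation`.
#' @export
convergenceStudy <- function(record, window_lengths, alpha = NULL) {
  X <- recordData(record)
  n <- nrow(X); T <- ncol(X)
  if (max(window_lengths) > T) stop("max window exceeds record length")
  if (is.null(alpha))
    alpha <- vapply(seq_len(n),
                    function(i) as.numeric(estimateAlpha(X[i, ])), numeric(1))
  Afull <- fitCoupling(X, alpha)
  nf <- sqrt(sum(Afull^2))
  keep <- window_lengths >= n + 2L
  if (any(!keep))
    message(sum(!keep), " window(s) below the feasibility bound skipped")
  dev <- vapply(window_lengths[keep], function(w) {
    Aw <- fitCoupling(X[, seq_len(w), drop = FALSE], alpha, J = w)
    sqrt(sum((Aw - Afull)^2)) / nf
  }, numeric(1))
  data.frame(window = window_lengths[keep], rel_deviation = dev)
}
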