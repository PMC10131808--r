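# Synthetic generators: exact fractional Gaussian noise, binomial cascades
# with analytic generalized Hurst exponents, fractional coupled systems, and
# staged multi-clinic cohorts with record/patient/institution structure.

#' Exact fractional Gaussian noise
#'
#' Generates stationary fGn with Hurst exponent `hurst` by circulant
#' embedding (Davies-Harte), so the sample autocovariance is exact in
#' expectation: gamma(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2.
#'
#' @param n series length (>= 2).
#' @param hurst Hurst exponent in (0, 1). `hurst = 0.5` is white noise.
#' @param seed integer seed.
#' @return numeric vector of length `n`, unit marginal variance.
#' @examples
#' x <- genFgn(1024, hurst = 0.7, seed = 1)
#' @export
genFgn <- function(n, hurst, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly in (0, 1)")
  if (n < 2) stop("'n' must be >= 2")
  set.seed(seed)
  H2 <- 2 * hurst
  gam <- function(k) 0.5 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
  m <- 2L * n
  # first row of the circulant embedding of the n x n Toeplitz covariance
  cc <- c(gam(0:(n - 1L)), gam(n), gam((n - 1L):1))
  lam <- Re(fft(cc))
  lam[lam < 0 & lam > -1e-8] <- 0
  if (any(lam < 0)) stop("circulant embedding not nonnegative definite")
  half <- m %/% 2L
  z <- complex(length.out = m)
  z[1L] <- sqrt(lam[1L]) * rnorm(1)
  z[half + 1L] <- sqrt(lam[half + 1L]) * rnorm(1)
  j <- 2:half
  re <- rnorm(half - 1L); im <- rnorm(half - 1L)
  z[j] <- sqrt(lam[j] / 2) * complex(real = re, imaginary = im)
  z[m + 2L - j] <- Conj(z[j])
  Re(fft(z, inverse = FALSE))[seq_len(n)] / sqrt(m)
}

#' Theoretical fGn autocovariance
#'
#' @param k nonnegative integer lag(s).
#' @param hurst Hurst exponent in (0, 1).
#' @return gamma(k) for unit-variance fGn.
#' @export
fgnAutocov <- function(k, hurst) {
  H2 <- 2 * hurst
  0.5 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
}

#' Binomial multiplicative cascade
#'
#' Deterministic binomial cascade measure over 2^levels cells: each cell
#' splits in two, one child weighted `p`, the other `1 - p`. Its generalized
#' Hurst exponent has the closed form h(q) = 1/q - log2(p^q + (1-p)^q)/q
#' (q != 0), attached as the attribute `"hq"` (a function of q) for use as a
#' multifractal oracle. With `permute = TRUE` the side receiving `p` is
#' randomized per split (seeded); the multifractal spectrum is unchanged.
#'
#' @param levels number of dyadic refinement levels (>= 8); series length is
#'   2^levels.
#' @param p branch weight in (0, 1), exclusive; `p = 0.5` gives the uniform
#'   (monofractal) measure with h(q) = 1.
#' @param seed integer seed (used only when `permute = TRUE`).
#' @param permute randomize branch orientation per split.
#' @return numeric vector of length 2^levels (measure scaled to mean 1), with
#'   attributes `hq`, `p`, `levels`.
#' @export
genBinomialCascade <- function(levels, p, seed = 1L, permute = FALSE) {
  if (p <= 0 || p >= 1) stop("degenerate cascade: 'p' must be strictly in (0, 1)")
  if (levels < 8) stop("'levels' must be >= 8")
  set.seed(seed)
  w <- 1
  for (l in seq_len(levels)) {
    if (permute) {
      flip <- runif(length(w)) < 0.5
      a <- ifelse(flip, 1 - p, p)
    } else a <- rep(p, length(w))
    w <- as.vector(rbind(w * a, w * (1 - a)))
  }
  x <- w * 2^levels
  attr(x, "hq") <- function(q) 1 / q - log2(p^q + (1 - p)^q) / q
  attr(x, "p") <- p
  attr(x, "levels") <- levels
  x
}

#' Specification of one synthetic fractional coupled system
#'
#' @param n_channels state dimension n.
#' @param n_samples trajectory length T.
#' @param stage COPD stage label 0-4 carried into the record metadata.
#' @param alpha per-channel fractional orders (recycled to length n).
#' @param A_true n x n coupling matrix.
#' @param B_true n x p input matrix, p < n; `NULL` for no inputs.
#' @param u_kind `"none"`, `"sparse_impulses"` or `"sinusoid"`.
#' @param noise_sd process-noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param x0 initial state (defaults to zeros).
#' @return validated list of class `"SyntheticSpec"`; records the spectral
#'   radius of `A_true` for reproducibility.
#' @export
syntheticSpec <- function(n_channels, n_samples, stage = 0L,
                          alpha = rep(0.4, n_channels), A_true,
                          B_true = NULL, u_kind = c("none", "sparse_impulses",
                                                    "sinusoid"),
                          noise_sd = 0.1, seed = 1L, x0 = NULL) {
  u_kind <- match.arg(u_kind)
  alpha <- rep_len(alpha, n_channels)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (!all(dim(A_true) == c(n_channels, n_channels)))
    stop("'A_true' must be ", n_channels, " x ", n_channels)
  if (is.null(B_true)) B_true <- matrix(0, n_channels, 0L)
  if (ncol(B_true) >= n_channels)
    stop("input dimension p must be strictly smaller than n_channels")
  if (is.null(x0)) x0 <- rep(0, n_channels)
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), stage = as.integer(stage),
                 alpha = alpha, A_true = A_true, B_true = B_true,
                 u_kind = u_kind, noise_sd = noise_sd,
                 seed = as.integer(seed), x0 = rep_len(x0, n_channels),
                 spectral_radius = max(Mod(eigen(A_true,
                                                 only.values = TRUE)$values))),
            class = "SyntheticSpec")
}

# Draw the unknown-input sequence for a spec; p x (T-1), seeded by caller.
.makeInputs <- function(spec) {
  p <- ncol(spec$B_true); Tm1 <- spec$n_samples - 1L
  if (p == 0L || spec$u_kind == "none") return(matrix(0, max(p, 0L), Tm1))
  U <- matrix(0, p, Tm1)
  if (spec$u_kind == "sparse_impulses") {
    for (i in seq_len(p)) {
      k <- sort(sample.int(Tm1, max(3L, Tm1 %/% 100L)))
      U[i, k] <- rnorm(length(k), sd = 2)
    }
  } else {
    for (i in seq_len(p))
      U[i, ] <- sin(2 * pi * seq_len(Tm1) / (50 * i) + runif(1, 0, 2 * pi))
  }
  U
}

#' Simulate a fractional-order coupled system
#'
#' Integrates `Delta^alpha x[k+1] = A x[k] + B u[k] + eps[k+1]` under the
#' full-memory Grünwald-Letnikov operator: `x[k+1] = A x[k] + B u[k] +
#' eps[k+1] - sum_{j>=1} psi(alpha_i, j) x_i[k+1-j]`. With all `alpha = 1`,
#' `B = 0` and no noise this is exactly the VAR(1) recursion
#' `x[k+1] = A x[k]` (one-step memory).
#'
#' @param spec a [syntheticSpec()].
#' @param channels optional channel labels (default Ch1..Chn, or the preset
#'   labels when n matches a preset).
#' @param recordId,patientId,institution metadata carried into the record.
#' @return a [MultichannelRecord-class]. Attribute `"U"` holds the input
#'   sequence actually used.
#' @export
simulateFractionalSystem <- function(spec, channels = NULL,
                                     recordId = "synth", patientId = "P0",
                                     institution = "SIM") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_channels; T <- spec$n_samples
  U <- .makeInputs(spec)
  eps <- matrix(if (spec$noise_sd > 0) rnorm(n * T, sd = spec$noise_sd)
                else 0, n, T)
  eps[, 1L] <- 0
  X <- tryCatch(
    .gl_simulate_cpp(spec$A_true, spec$B_true, U, spec$alpha, eps, spec$x0,
                     1e9),
    error = function(e) stop("unstable synthetic spec (seed ", spec$seed,
                             ", stage ", spec$stage, "): ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(channels))
    channels <- if (n == 12L) channelPreset("nox12")
                else if (n == 6L) channelPreset("porti6")
                else paste0("Ch", seq_len(n))
  rec <- new("MultichannelRecord", data = X, channels = channels,
             recordId = recordId, patientId = patientId,
             institution = institution, stage = spec$stage,
             samplingNote = "nominal")
  attr(rec, "U") <- U
  rec
}

#' Specification of a staged synthetic cohort
#'
#' Describes a cohort emulating the structure of a multi-clinic COPD signal
#' collection: patients with stage labels 0-4 spread over institutions, a
#' handful of records per patient, and stage information injected through the
#' coupling matrix only. Per stage s the base coupling A0 is shifted by
#' `s * coupling_shift * D` along a fixed unit-Frobenius direction matrix D;
#' each patient adds a small random perturbation; each record is an
#' independent noisy simulation.
#'
#' @param n_patients number of patients.
#' @param records_per_patient records simulated per patient.
#' @param stage_proportions length-5 proportions over stages 0-4 (sum 1).
#' @param institutions institution labels, assigned round-robin to patients.
#' @param channel_preset `"nox12"` (12 channels) or `"porti6"` (6).
#' @param coupling_shift Frobenius-norm shift of the coupling matrix per
#'   stage step; 0 removes all stage signal (labels become unlearnable).
#' @param noise_sd process-noise sd of each simulated record.
#' @param n_samples samples per channel per record.
#' @param patient_sd per-entry sd of the patient-level coupling perturbation.
#' @param seed integer seed.
#' @return validated list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n_patients = 60L, records_per_patient = 5L,
                       stage_proportions = rep(0.2, 5),
                       institutions = c("VB", "MD1", "MD2", "CP"),
                       channel_preset = c("nox12", "porti6"),
                       coupling_shift = 0.1, noise_sd = 0.1,
                       n_samples = 6000L, patient_sd = 0.002, seed = 1L) {
  channel_preset <- match.arg(channel_preset)
  if (abs(sum(stage_proportions) - 1) > 1e-9)
    stop("'stage_proportions' must sum to 1")
  if (length(stage_proportions) != 5L)
    stop("'stage_proportions' must have length 5")
  structure(list(n_patients = as.integer(n_patients),
                 records_per_patient = as.integer(records_per_patient),
                 stage_proportions = stage_proportions,
                 institutions = institutions,
                 channel_preset = channel_preset,
                 coupling_shift = coupling_shift, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), patient_sd = patient_sd,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Fixed unit-Frobenius direction matrix for the stage shift; deterministic in
# n so cohorts of the same preset share it.
.stageDirection <- function(n) {
  D <- matrix(cos(seq_len(n * n)), n, n)
  D / sqrt(sum(D^2))
}

#' Generate a staged synthetic cohort
#'
#' Allocates patients to stages per `stage_proportions` (largest-remainder
#' rounding), assigns institutions round-robin, and simulates every record
#' with [simulateFractionalSystem()]. The base coupling is
#' `A0 = -0.5 I + N(0, 0.08^2)` (spectral abscissa below zero, so the
#' fractional dynamics are mean-reverting); per-channel fractional orders are
#' fixed at `0.25 + 0.03 * (channel - 1)` and identical across stages, so the
#' stage signal lives in the coupling matrix alone.
#'
#' @param spec a [cohortSpec()].
#' @return list of [MultichannelRecord-class] objects with attribute
#'   `"A_stage"` (the five stage-level coupling matrices) and `"alpha"`.
#' @export
genStagedCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- if (spec$channel_preset == "nox12") 12L else 6L
  labels <- channelPreset(spec$channel_preset)
  # largest-remainder allocation of patients to stages
  raw <- spec$stage_proportions * spec$n_patients
  cnt <- floor(raw)
  rem <- spec$n_patients - sum(cnt)
  if (rem > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[idx] <- cnt[idx] + 1L
  }
  if (any(cnt == 0 & spec$stage_proportions > 0))
    stop("infeasible stage_proportions: a requested stage received 0 patients")
  stages <- rep(0:4, times = cnt)
  alpha <- 0.25 + 0.03 * (seq_len(n) - 1L)
  A0 <- -0.5 * diag(n) + matrix(rnorm(n * n, sd = 0.08), n, n)
  D <- .stageDirection(n)
  A_stage <- lapply(0:4, function(s) A0 + s * spec$coupling_shift * D)
  inst <- rep_len(spec$institutions, spec$n_patients)
  records <- vector("list", spec$n_patients * spec$records_per_patient)
  r <- 0L
  for (pat in seq_len(spec$n_patients)) {
    s <- stages[pat]
    Apat <- A_stage[[s + 1L]] +
      matrix(rnorm(n * n, sd = spec$patient_sd), n, n)
    for (k in seq_len(spec$records_per_patient)) {
      r <- r + 1L
      sub <- syntheticSpec(n_channels = n, n_samples = spec$n_samples,
                           stage = s, alpha = alpha, A_true = Apat,
                           noise_sd = spec$noise_sd,
                           seed = (spec$seed * 10007L + r) %% 2147483647L)
      records[[r]] <- simulateFractionalSystem(
        sub, channels = labels,
        recordId = sprintf("R%04d", r),
        patientId = sprintf("P%03d", pat),
        institution = inst[pat])
    }
  }
  attr(records, "A_stage") <- A_stage
  attr(records, "alpha") <- alpha
  records
}
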