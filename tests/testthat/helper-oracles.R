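# Independent brute-force oracles and shared (lazily built) fixtures.

# GL coefficients straight from the gamma-ratio definition (valid for
# non-integer alpha; R's gamma() handles negative non-integer arguments).
oracle_gl_gamma <- function(alpha, J) {
  vapply(0:J, function(j) gamma(j - alpha) / (gamma(-alpha) * gamma(j + 1)),
         numeric(1))
}

# Direct truncated convolution sum_{j=0}^{min(k-1,J)} psi[j] x[k-j].
oracle_conv <- function(x, psi) {
  J <- length(psi) - 1L
  vapply(seq_along(x), function(k) {
    m <- min(k - 1L, J)
    sum(psi[1:(m + 1L)] * x[k - (0:m)])
  }, numeric(1))
}

# Classical DFA fluctuation function at one scale: plain lm() per window.
oracle_dfa_f2 <- function(x, s) {
  Y <- cumsum(x - mean(x))
  Ns <- floor(length(Y) / s)
  msq <- vapply(seq_len(Ns), function(v) {
    idx <- ((v - 1L) * s + 1L):(v * s)
    tt <- seq_len(s)
    mean(resid(lm(Y[idx] ~ tt))^2)
  }, numeric(1))
  sqrt(mean(msq))
}

# Layer-by-layer parameter enumeration: materialize every weight/bias array
# shape and count elements.
oracle_count_dense_stack <- function(dims) {
  total <- 0L
  for (l in seq_len(length(dims) - 1L))
    total <- total + length(matrix(0, dims[l], dims[l + 1L])) +
      length(numeric(dims[l + 1L]))
  total
}
oracle_count_baseline <- function(bs) {
  total <- 0L
  for (ly in bs$layers) {
    total <- total + switch(ly$type,
      dense = length(matrix(0, ly$in_dim, ly$units)) +
        length(numeric(ly$units)),
      conv1d = length(array(0, c(ly$kernel, ly$in_channels, ly$filters))) +
        length(numeric(ly$filters)),
      lstm = length(array(0, c(ly$in_dim, 4L * ly$units))) +
        length(array(0, c(ly$units, 4L * ly$units))) +
        length(numeric(4L * ly$units)),
      0L)
  }
  total
}

# One-vs-rest metric counting by direct enumeration over all pairs.
oracle_ovr_metrics <- function(truth, pred, classes) {
  sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      precision = tp / (tp + fp))
  })
}

# Small 4-channel system shared by the identification tests.
make_test_system <- function() {
  set.seed(42)
  n <- 4L
  list(n = n,
       A = -0.5 * diag(n) + matrix(rnorm(n * n, sd = 0.1), n, n),
       alpha = c(0.3, 0.4, 0.5, 0.45))
}

# Lazily built expensive fixtures, shared across test files.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fixture_cohort_dataset <- function() {
  fixture("cohort_ds", function() {
    rec <- genStagedCohort(cohortSpec(seed = 11))
    buildStagedDataset(rec, "nox12")
  })
}

fixture_small_record <- function() {
  fixture("small_record", function() {
    set.seed(9)
    n <- 12L
    A <- -0.5 * diag(n) + matrix(rnorm(n * n, sd = 0.08), n, n)
    sp <- syntheticSpec(n, 1500L, stage = 2L, alpha = rep(0.4, n),
                        A_true = A, noise_sd = 0.1, seed = 9)
    simulateFractionalSystem(sp, channels = channelPreset("nox12"),
                             recordId = "R1", patientId = "P1",
                             institution = "VB")
  })
}
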