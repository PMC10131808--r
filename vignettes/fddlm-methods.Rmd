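---
title: "Fractional dynamics and deep-learning staging of COPD signals: methods"
author: "fddlm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional dynamics and deep-learning staging of COPD signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fddlm)
```

## The problem

Chronic obstructive pulmonary disease (COPD) is staged 0 (no COPD) to 4
(very severe) from spirometry: a ratio FEV1/FVC below 0.70 establishes
airflow limitation, and the FEV1 percent of predicted sets the stage
(`stageFromSpirometry()`). Spirometry demands trained personnel and good
patient effort, which makes population-scale and early-stage screening
unreliable. An alternative is to stage the disease from overnight
multichannel physiological recordings — breathing-effort belts (thorax,
abdomen), pulse oximetry (SpO2, pulse, plethysmograph), nasal pressure and
derived channels — acquired by portable polygraphs with 12-channel
(`"nox12"`) or 6-channel (`"porti6"`) rosters.

This package implements that pipeline in three layers:

1. **Multifractal characterization** of single channels (MF-DFA with focus
   points and generalized Hurst exponents), which motivates the modeling:
   healthy physiological signals are typically multifractal, while severe
   disease narrows the spectrum.
2. **Fractional-order coupled dynamics**: a discrete linear state model
   under the Grünwald–Letnikov (GL) fractional difference, whose coupling
   matrix **A** summarizes the interdependencies between channels. The
   flattened **A** (144 values for 12 channels, 36 for 6) is the record's
   feature vector.
3. **A feedforward softmax classifier** on those features, evaluated by
   k-fold cross-validation, leave-one-institution-out hold-out, and a
   reduced-channel (36-input) transfer configuration.

Because the clinical recordings this methodology was developed on are not
publicly deposited, the package ships a first-class synthetic-data module
that emulates their structure (records × patients × institutions × stages)
with fully known ground truth, so every stage of the pipeline is testable.

## Multifractal detrended fluctuation analysis

For a bounded series $X(i)$, $i = 1..L$, the cumulative profile is
$Y(t) = \sum_{i \le t} (X(i) - \langle X \rangle)$
(`fluctuationProfile()`). The profile is divided into $N_s = \lfloor L/s
\rfloor$ non-overlapping windows of length $s$; in each window $v$ a local
least-squares polynomial trend $y_v$ (straight line by default) is removed
and the fluctuation is the RMS residual

$$F(v, s) = \sqrt{\tfrac1s \sum_{i=1}^{s} \{Y[(v-1)s + i] - y_v(i)\}^2}$$

(`windowFluctuation()`). The moment-wise scaling function is

$$S_F(q, s) = \Big\{ \tfrac1{N_s} \sum_v F(v,s)^q \Big\}^{1/q},$$

computed over a grid of moment orders $q$ and scales $s$
(`scalingFunction()`). Taking the whole signal as a single window, $N_L =
1$, makes $S(q, L) = F(1, L)$ independent of $q$: the **focus point**. For
a multifractal signal the per-$q$ regression lines of $\log S(q,s)$ on
$\log s$ converge toward the focus; the slopes are the generalized Hurst
exponents $H(q)$ (`hurstCurve()`), constant in $q$ for monofractals and
decreasing for multifractals. Two fit modes are provided because the
literature uses both: independent per-$q$ OLS, and a focus-constrained
regression in which every line is forced through $(\log L, \log S(q,L))$.
Group-level curves carry a t-based 95% band on the per-$q$ mean
(`groupHurstBand()`), and curves are compared by the first Wasserstein
distance between their value sets (`hqWasserstein()`), i.e. the area
between empirical quantile functions.

Numerical choices:

* **Scales**: 16 log-spaced window lengths from 16 to $L/4$ by default;
  the window budget (at least 4 windows at the largest scale) keeps the
  moment average meaningful.
* **Windows** are taken from the series start only; no reversed second
  pass. This is configurable through explicit `scales`.
* **$q = 0$** is excluded from the default grid $\{-5,-3,-1,1,3,5\}$; when
  requested it is evaluated by the logarithmic-average limit
  $\exp(\mathrm{mean}\,\log F)$.
* **Zero-fluctuation windows** (possible on constant stretches) would make
  negative-$q$ moments infinite; they are dropped from the moment sum and
  counted in the surface's `droppedWindows` slot.
* **Known finite-size behavior**: on finite monofractal fGn the estimated
  $H(q)$ acquires a small spread (of order $+0.02$ at $q=-5$ for $n =
  2^{12}$–$2^{14}$). Tests therefore compare group bands against
  independently replicated finite-sample means rather than asymptotic
  values at extreme $q$.

## The fractional-order coupled model

The state model for an $n$-channel record $x[k] \in \mathbb{R}^n$ is

$$\Delta^{\alpha} x[k+1] = A\,x[k] + B\,u[k], \qquad y[k] = C\,x[k],$$

where $\Delta^{\alpha}$ applies the GL fractional difference of order
$\alpha_i$ to channel $i$:

$$\Delta^{\alpha_i} x_i[k] = \sum_{j=0}^{k} \psi(\alpha_i, j)\, x_i[k-j],
\qquad \psi(\alpha, j) = \frac{\Gamma(j - \alpha)}{\Gamma(-\alpha)\,
\Gamma(j+1)}.$$

The weights are computed by the stable recursion $\psi(\alpha, j) =
\psi(\alpha, j{-}1)(j{-}1{-}\alpha)/j$ (`glCoeffs()`), which agrees with
the gamma-ratio form to machine precision. $\alpha = 1$ gives one-step
memory ($x[k+1] = (I + A)x[k]$, the classic linear time-invariant case);
fractional $\alpha$ weights the entire history with slowly decaying
coefficients — the long-range-memory mechanism. With 6000-sample records
the full history is used exactly (`memory_J` = record length); truncation
is exposed for longer series.

**Identification.** Per-channel orders are estimated first
(`estimateAlpha()`): the default maps the DFA Hurst estimate through the
ARFIMA correspondence $\alpha = H - 1/2$; a log-periodogram (GPH)
estimator is the alternative. The method the original methodology defers
to is wavelet-based and is not reproduced here; both provided estimators
are standard, documented, and selectable. Given $\alpha$, the coupling
matrix solves the row-wise least squares $\min_A \sum_k \| z[k{+}1] - A
x[k] \|^2$ with $z = \Delta^{\alpha} x$ (`fitCoupling()`); a rank-deficient
Gram matrix triggers a tiny logged ridge so degenerate inputs cannot crash
the pipeline.

**Unknown inputs.** Unobserved stimuli enter through $B u[k]$ with $p < n$.
`fitUnknownInputs()` alternates (i) least squares for $A$ given the input
term with (ii) re-estimation of the input term from the residual sequence.
A subtlety drove the design here: the unrestricted top-$p$ SVD of the
full residual is a *fixed point* of this alternation — the least-squares
residual is orthogonal to the regressor rows, so its leading factors can
never feed back into $A$. The input term is therefore factored only on the
residual's highest-energy time columns (5% by default), encoding the
assumption that unobserved stimuli are intermittent; a descent guard keeps
the previous estimate whenever a candidate fails to lower the objective,
so the recorded residual norms are non-increasing by construction. With
$p = 0$ the routine reduces exactly to `fitCoupling()`. This is a
deliberately simple, testable surrogate for the expectation-maximization
treatment in the source literature, not a reproduction of it.

**Features.** `extractFeature()` flattens $\hat A$ row-major into 144 (or
36) values; min–max normalization to $[0,1]$ is a dataset-level step fit on
training data only (`normalizeFeatures()`), so no information leaks from
test folds. Whether the feature should also include $\hat\alpha$ is
ambiguous in the source material; $144 = 12^2$ implies the coupling matrix
alone, which is what is used.

`convergenceStudy()` refits $A$ on nested record prefixes and reports the
relative Frobenius deviation from the full-record fit — the practical
check behind using recordings of modest length (about 10 minutes of
signal) for staging.

## The classifier

`netSpec()` describes the staging network: input (144 or 36) → 300
rectifier units → dropout 0.2 → 100 rectifier units → dropout 0.2 →
softmax over 5 stages; rmsprop (decay 0.9) on the categorical
cross-entropy, batch size 64, 500 epochs by default. The closed-form
trainable-parameter count (`countParams()`) for the 144-input network is
74,105. Training (`trainFddlm()`) is implemented directly in R matrix
code — at these input sizes a 500-epoch fit takes seconds — with He
initialization, per-epoch shuffling and inverted dropout, all seeded so a
spec plus data reproduces identical weights. Early stopping on a
validation split is available but off by default.

The learning rate is stated as both 0.001 and 0.0001 in different places
in the source material; the default here is 0.001, configurable.

Baselines trained on raw signals rather than coupling features (flattened
72000-sample dense network, 300-unit LSTM on 6000×12, 1-D CNN on 72000×1)
are provided as architecture builders for parameter-count parity
(`buildBaseline()`), not for training. The CNN's printed count of
147,456,453 parameters is reproduced only by kernel width 3 with
length-preserving padding — that setting was reverse-engineered from the
count and is documented as such. The stated LSTM layers give a computed
count of 406,205 against a published 535,805; the builder reports the
computed value and flags the discrepancy rather than forcing agreement.
`linearProbe()` (multinomial logistic regression on the same normalized
features, k-fold) serves as an independent linear-separability reference.

## Evaluation protocols

* **k-fold** (`kfoldEval()`, $k=5$): seeded shuffle, disjoint folds, train
  on $k-1$, test on 1, rotate; plain shuffled splits by default (stratified
  splitting is deliberately not silently applied), with an optional
  per-patient grouping that never splits a patient's records across folds.
  Feature scaling is refit inside every training fold.
* **Hold-out** (`holdoutEval()`): all records of one institution form the
  test set; optional seeded over/under-sampling balances training classes
  to the median class count.
* **Transfer**: the 6-channel preset produces 36-dimensional features and a
  36-input network; the protocol is otherwise identical.
* **Metrics** (`metricsFromConfusion()`): one-vs-rest sensitivity,
  specificity and precision per stage; undefined ratios are reported as
  `NA`, never as 0. AUROC is macro-averaged one-vs-rest over softmax
  scores (the multi-class AUROC definition is not fixed by the source
  material; macro averaging is the common default).

## The synthetic cohort generator

`genStagedCohort()` emulates the *structure* of a multi-clinic COPD
recording collection, not respiratory waveform morphology: no apnea
events, no pulse shapes — only the statistical structure the pipeline
consumes. Its defaults are fixed study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| patients × records | 60 × 5 | a working-set size comparable to a single-clinic collection; 300 records |
| samples/channel | 6000 | matches the classifier baselines' input reshape; ~10 min at 10 Hz |
| stage proportions | uniform | balanced 5-class problem |
| institutions | VB, MD1, MD2, CP round-robin | four clinics, institution-invariant generative process |
| base coupling $A_0$ | $-0.5 I + \mathcal{N}(0, 0.08^2)$ | spectral abscissa < 0: mean-reverting, stable fractional dynamics |
| stage shift | $s \cdot 0.1 \cdot D$, $\|D\|_F = 1$ | stage signal lives in **A** only; orders $\alpha$ identical across stages |
| patient perturbation | entrywise sd 0.002 | patient idiosyncrasy well below the stage separation |
| process noise sd | 0.1 | drives the stationary dynamics; keeps coupling estimation error below the stage gap at $T = 6000$ |
| orders $\alpha$ | 0.25 + 0.03·(channel−1) | heterogeneous long-memory across channels, all stationary-side |

With these conditions the cohort is separable by construction: the
per-stage coupling matrices differ by 0.1 in Frobenius norm per stage step,
while coupling-estimation noise projects onto any single discriminant
direction at roughly an order of magnitude less. Setting `coupling_shift =
0` removes all stage information and drives every classifier to chance
(20% on balanced labels) — the negative control. Because the stage signal
is a single direction in feature space with added estimation noise, a
*linear* probe does not saturate under the default conditions (it sits
around 80%); the probe reaches 90%+ under a wider shift (e.g. 0.3), which
is how the linear-separability check is exercised.

Generators are exact where exactness is testable: fGn comes from circulant
embedding (Davies–Harte), so its autocovariance matches the closed form
$\gamma(k) = \frac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$ in
expectation, and the binomial cascade carries its analytic generalized
Hurst exponent $h(q) = 1/q - \log_2(p^q + (1-p)^q)/q$ as metadata — the
multifractal oracle for MF-DFA validation. The fractional simulator is
validated against a brute-force GL recursion written independently of the
fast kernel.

What passing these tests does **not** show: robustness to real-world
artifacts (sensor dropout, movement, apnea events, inter-device frequency
differences), to label noise in clinical staging, or to distribution shift
beyond the institution-invariant case simulated here. Real hold-out
degradation caused by clinic-level imbalance is specifically *not*
represented, because institutions are statistically identical in the
generator.

## Problem sizes and runtime

All shipped checks run on a single CPU: MF-DFA fixtures use series of
$2^{12}$–$2^{14}$ samples; identification fixtures use 4-channel systems
of 2000–4096 samples; cohort-level checks use the 60×5 default (300
records of 12×6000) plus a 30×4 negative control, with networks trained
for 80 epochs during evaluation — reduced from the 500-epoch default,
which these small, well-separated cohorts do not need.

## Known limitations

* The unknown-input step is a surrogate with a column-support heuristic;
  it is not the EM estimator of the source literature, and for *dense*
  persistent inputs (e.g. sinusoidal drive) its support restriction limits
  how much of the input it can absorb.
* $\alpha$ estimation on coupled, mean-reverting channels is biased toward
  0 (mean reversion masks long memory at large scales); the pipeline's
  staging accuracy is insensitive to this because the bias is consistent
  across records, but the estimates should not be read as unbiased
  physiological orders.
* EDF device files are not read directly; records are exchanged as CSV
  (samples × channels) plus a cohort manifest.
* The singularity spectrum $f(\alpha)$ / Legendre transform is out of
  scope; only $H(q)$ is reported.
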