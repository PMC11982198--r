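---
title: "Detecting population drift with a one-class SVM frontier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting population drift with a one-class SVM frontier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftguard)
```

## The problem

A clinical prediction model is trained on one patient population and then
deployed into another. When the deployment-time distribution of input
features no longer matches the training distribution — population drift,
or covariate shift: $P_{\mathrm{train}}(X) \neq P_{\mathrm{deploy}}(X)$ —
the model's accuracy claims silently stop applying. Detecting this is
hard in practice because ground-truth labels for new patients arrive late
or never, so performance cannot simply be tracked.

driftguard implements an unsupervised detector: a one-class support
vector machine (OCSVM) is fitted to the same prepared training matrix the
diagnostic model was developed on, and every deployment-time record is
scored against the learned frontier. Records inside the frontier are
consistent with the training population; records outside are individual
drift signals, available in real time and without labels.

## The model

The frontier is the Schölkopf $\nu$-OCSVM with an RBF kernel
$K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2)$. The fitted model is the
set of support vectors $x_i$, nonnegative dual weights $\alpha_i$ and
offset $\rho$, and the signed decision function

$$ f(x) = \sum_i \alpha_i \, e^{-\gamma \lVert x - x_i \rVert^2} - \rho, $$

with $f(x) \ge 0$ classified as *inlier*. At the optimum the duals
satisfy $0 \le \alpha_i \le 1/(\nu n)$ and $\sum_i \alpha_i = 1$, and
$\nu$ has its usual double role: it upper-bounds the fraction of training
records outside the frontier and lower-bounds the support-vector
fraction. The quadratic programme is solved by libsvm (through
**e1071**); everything else — decision evaluation, serialisation,
scoring, monitoring — runs off the stored fields, so a written model file
is self-sufficient.

Tunable parameters:

* `nu` (unitless fraction, default **0.01**): the assumed training
  contamination; 1% mirrors a development setting where the training
  cohort is curated but not perfect.
* `gamma` (inverse squared feature units, default **1/p**): on
  standardised features every dimension has unit variance, so $1/p$ is
  the canonical "automatic" width and coincides with variance-normalised
  scaling ($1/(p \cdot \mathrm{Var})$ with $\mathrm{Var} = 1$). An
  explicit positive value can be supplied instead.

## The preparation chain

`prepare()` reproduces the standard development preprocessing, and its
output `preprocess_model` is the exact transform every deployment-time
record must pass through (`transform_new()`):

1. **Multicollinearity pruning** (`prune_collinear()`, threshold
   $|r| > 0.9$): a greedy scan in canonical column order drops any
   feature whose absolute Pearson correlation with an already-retained
   feature exceeds the threshold. The scan order is a genuine design
   choice — no order is canonical a priori — and the greedy
   first-conflict rule in canonical WDBC column order is used because it
   is deterministic and, on the real cohort, removes exactly the nine
   features known to be redundant there (perimeter/area mean, se and
   worst, radius_worst, texture_worst, concave points_mean), leaving 21.
   Correlations are computed on the original labelled records, before any
   oversampling.
2. **SMOTE balancing** (`smote_oversample()`): the minority class is
   oversampled to the majority count by interpolation,
   $s = x_i + g\,(x_{nn} - x_i)$ with $x_{nn}$ one of the $k$ nearest
   minority neighbours and $g \sim U[0,1]$. Default $k = 5$, the original
   SMOTE setting. Distances are Euclidean on the unscaled pruned
   features, because balancing precedes scaling in the chain; this makes
   neighbour choice scale-sensitive, which is accepted as part of the
   emulated workflow. On the WDBC cohort this creates 145 synthetic
   malignant records: 714 in total, 357 per class.
3. **Label removal and z-scoring** (`fit_scaler()`): features are
   standardised with per-feature mean and *population* SD (divisor $n$).
   At $n = 714$ the divisor choice is numerically irrelevant, but it must
   be fixed once for bit-reproducibility.

## The drift simulator

`simulate_drift()` builds drifted populations at the edges of the
training distribution. For the anchor feature (default `radius_mean`,
a strong class separator), the full training rows attaining its minimum
and maximum are taken as anchor rows; the low/high cohort centres are
those rows with the anchor coordinate pushed a further `offset_sd`
(default **0.4**) training SDs outward. Each cohort then adds independent
Gaussian noise with SD `noise_frac` (defaults **0.05, 0.10, 0.30**) of
the training SD to *every* feature, `n_per_side` = 5,000 records per side
— 10,000 records per noise level.

All of this happens in the scaled feature space, where every training SD
is 1, so "0.4 SD" and "5% of SD" are literally 0.4 and 0.05. Working in
raw units with the training scaler's SDs would be equivalent up to which
SD estimate is used; the scaled-space definition is chosen because it
makes "SD" unambiguous across features. Low
centres drift toward early-stage (benign-like) populations, high centres
toward late-stage (malignant-like) ones. Noise is independent across
features — no attempt is made to preserve the training covariance, which
is a known limitation of this simulation design. Ties at the anchor
extremum break to the first occurrence.

`evaluate_cohorts()` tabulates, per noise level, how many simulated
records the frontier accepts as inliers. The expected signature of a
drift-sensitive detector is a *monotone increase* of inlier counts with
noise: noisier drifted populations overlap the training cloud more, so
more of their records land inside the frontier. Because the oversampling
draw and the noise draws are stochastic, counts vary across seeds and
only their order of magnitude and monotone trend are stable quantities.

## The deployment monitor

The per-record rule is binary. A deployable monitor needs an explicit
aggregation criterion, so `monitor_stream()` adds one (a deployment
convenience this package layers on top of the per-record rule):
within a trailing window of $W$ records (default 100), an alert is
raised when the outlier count exceeds the one-sided binomial critical
value for the no-drift rate `nu_ref` (default: the model's $\nu$) at
level `alert_alpha` (default 0.01), i.e. the smallest $c$ with
$P(\mathrm{Bin}(W, \nu_{\mathrm{ref}}) > c) \le \alpha$. Under-full
windows never alert. Under no drift the per-window alert probability is
at most $\alpha$ by construction; consecutive sliding windows share
records, so alerts arrive in runs when drift is real.

## The synthetic cohort generator

`generate_cohort()` / `generate_wdbc_shaped()` produce WDBC-like
labelled cohorts so the entire pipeline is testable with no external
data. The preset emulates the structural features the pipeline actually
exercises:

* two classes with the 357:212 imbalance, 30 canonical feature names,
  positive values (positivity by a constant shift, which preserves
  correlations exactly, rather than truncation, which would not);
* nine features planted as near-collinear children
  ($r = 0.95$, built as $r \cdot z_{\mathrm{parent}} +
  \sqrt{1 - r^2}\,\varepsilon$ on the analytically standardised parent)
  of retained features, positioned after their parents in column order,
  so pruning removes exactly the planted nine;
* class-separating mean shifts on radius, texture, compactness and
  concavity means (malignant larger), so the anchor separates classes;
* a shared latent severity factor with moderate loadings (pairwise
  feature correlations ≈ 0.2–0.7, safely below the pruning threshold)
  and Student-t(4) tails, standardised to unit variance. Real
  morphometric features are strongly inter-correlated and right-skewed;
  the consequence that matters here is that a record extreme on the
  anchor is jointly extreme on correlated features and stands clear of
  the bulk, so the drift anchors are genuinely peripheral. With
  independent Gaussian features this fails in a qualitative way: in 21
  nearly independent dimensions a one-coordinate extreme is usually *not*
  among the most peripheral records, entire simulated cohorts can land
  inside the frontier, and inlier counts stop being monotone in noise.

What the generator does **not** emulate: the real marginal
distributions, the full 30 × 30 covariance matrix, or any image-derived
measurement process. Tests passing on synthetic cohorts therefore
demonstrate the pipeline's mechanics and its qualitative drift
behaviour, not clinical performance on real patients.

## Numerical choices

* **Margin resolution.** Free support vectors sit exactly on the frontier
  at the QP optimum; at the solver's KKT tolerance their computed
  decision values land at $\pm\sim 10^{-9}$ with arbitrary sign.
  `classify()` treats $|f(x)| \le 10^{-6}$ as on-the-frontier and
  resolves it as *inlier* (the inclusive boundary rule). The band is
  three orders of magnitude above the observed jitter and three below
  any decision value that matters downstream.
* **Solver tolerance** defaults to $10^{-7}$ (libsvm's default
  $10^{-3}$ leaves visibly sloppy duals at $n = 714$).
* **Serialisation** uses 17 significant digits, the smallest count at
  which every IEEE double survives a text round-trip exactly; model
  write/read is therefore an identity on decision values.
* **Seeding.** Every stochastic operation takes an explicit integer
  seed; `run_pipeline()` derives per-stage seeds from one master seed via
  a fixed affine map mod $2^{31}-1$ (`derive_seed()`), and seeded
  operations save and restore the caller's RNG state.
* **Degenerate inputs** fail loudly and early: missing values are
  located by row and column, constant features make correlation and
  scaling undefined and are hard errors, empty cohorts and truncated or
  version-mismatched model files are rejected.

## Problem sizes in the test suite

The suite exercises the full study-scale configuration (569-record
cohorts, 714 × 21 prepared matrices, 10,000 simulated records per noise
level, means over 10 master seeds) on both the bundled real data and the
synthetic preset; unit-level oracles (brute-force kernel sums, exhaustive
k-NN checks, loop-form pruning) run on small instances of 10–120 records
where exhaustive recomputation is natural. The whole suite completes in
well under a minute.

## Limitations

* The detector flags *covariate* novelty only; drift in the
  label-given-features relationship with an unchanged feature
  distribution is invisible to it.
* Decision values are used only through their sign (plus the numerical
  margin); calibrating them into continuous drift scores is out of
  scope.
* The simulator drifts one anchor feature with independent noise;
  covariance-preserving or multi-anchor drift is not modelled.
* The windowed binomial alert assumes record exchangeability within a
  window and a trustworthy `nu_ref`; a grossly misspecified `nu_ref`
  shifts the false-alarm rate accordingly.
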