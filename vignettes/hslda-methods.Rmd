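---
title: "Hierarchical supervised topic models for coded patient records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical supervised topic models for coded patient records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hslda)
```

## The model

A coded patient record — for instance a hospital discharge record after
guideline-driven discretization — is a bag of *feature-value pairs*: the
clinical feature (heart rhythm, LDL-C, smoking status, ...) together with
its discretized level (sinus, abnormal, yes, ...). `hslda` fits a
four-layer supervised topic model to a corpus of such records, each
carrying one diagnosis class out of `C`.

Each of `K` topics is a pair of distributions: a multinomial `pi[k, ]`
over the `F` features and, for every feature `f`, a multinomial over that
feature's block of values (the rows of `beta[k, ]`, block-normalized). A
record with `N` tokens is generated as

1. topic proportions `theta ~ Dirichlet(alpha)`;
2. for each token `n`: topic `r_n ~ Mult(theta)`, feature
   `f_n ~ Mult(pi[r_n, ])`, value `v_n ~ Mult(beta[r_n, block(f_n)])`;
3. class `y ~ softmax(eta %*% rbar)`, where
   `rbar = (1/N) * sum_n onehot(r_n)` is the empirical topic frequency and
   `eta` is a `C x K` coefficient matrix.

The class is driven by the *realized* topic assignments, not by `theta`:
two records with the same underlying proportions but different sampled
topics can receive different class probabilities, exactly as in
multi-class supervised LDA. The hierarchy (topic chooses a feature, then a
value within it) is the only difference from the flat three-layer model;
setting `F = 1` recovers multi-class sLDA exactly, which the package
exposes as `flatten_corpus()` / `baseline = "mslda"` and uses as its
comparison arm.

## Inference

The exact posterior over `(theta, r)` is intractable, so each document is
fit with a mean-field family `q(theta) prod_n q(r_n)` parameterized by a
Dirichlet vector `gamma` and per-token responsibility vectors `phi_n`.
The evidence lower bound (ELBO) consists of the Dirichlet cross-entropy,
the token terms, the response term and the entropy. Two points deserve
mention because they are where implementations of this model genuinely
differ:

* **The response normalizer.** The term
  `E_q[log sum_l exp(eta_l' rbar)]` has no closed form. We upper-bound it
  by `log E_q[sum_l ...]` (Jensen), which factorizes over tokens because
  `rbar` is a mean of independent one-hots under `q`. The resulting bound
  is what `elbo_doc()` reports, so every reported value is a true lower
  bound on the log evidence — the oracle tests rely on this.
* **The token update.** The bound's normalizer term is *linear* in any
  single `phi_n` with coefficient vector `h` (`compute_h()`), so the
  coordinate update linearizes `-log(h' phi_n)` at the current point
  (an MM step) and lands on a softmax:
  `phi_{n,i} proportional to pi[i, f_n] beta[i, v_n] exp(E[log theta_i] +
  eta[y,i]/N - h_i / (h' phi_n_old))` for unit weights. The expectation
  `E[log theta_i]` is `digamma(gamma_i) - digamma(sum gamma)`; only this
  choice makes the sweep a coordinate ascent on the bound, which the
  monotonicity tests verify directly.

The Dirichlet update is the usual `gamma = alpha + sum_n w_n phi_n`. At
test time the class is unknown, so the two response-coupled terms are
dropped and the update becomes closed-form — the same protocol multi-class
sLDA uses for held-out documents.

The M-step is closed-form for `pi` and `beta` (responsibility-weighted
count tables, with a configurable smoothing floor `epsilon = 1e-10` so
logs stay finite) and numeric for `eta`: the response objective is
maximized by Polak-Ribiere conjugate gradients with the analytic gradient,
with an L2 penalty `lambda * ||eta||^2` (default `lambda = 0.01`) because
softmax scores are invariant to shifting all class rows. A guard keeps the
previous `eta` if the penalized step would lower the objective, so EM
never moves backwards through the M-step.

### Token weights

TF-IDF weighting (`tfidf_weight()`, `tf * ln(D/df)` with a `1e-8` floor
for ubiquitous pairs) attaches a positive weight to every token. Weights
scale each token's sufficient statistics and replace `1/N` by `w_n/W` in
all response-coupled terms; with unit weights every formula reduces to the
unweighted model. One consequence of carrying the weights into the token
entropy (necessary for the closed-form `gamma` and M-step updates to stay
exact) is that the labeled token update divides the response terms by
`w_n`; at unit weights this is invisible, and it is what keeps the
weighted E-step a true coordinate ascent.

## Local optima and restarts

The bound is multi-modal in `(pi, beta)`. `hslda_config(n_init = r)` runs
`r` short seeded pilots (at most 8 EM iterations each), keeps the
initialization with the best bound and runs it to convergence — the
"short runs" selection strategy familiar from Gaussian-mixture EM. In the
package's own recovery experiments the final bound and the recovery error
correlate strongly, which is why the experiment protocols below use
`n_init = 3`; single-start fits are the default because they are three
times cheaper and adequate for exploration.

## The Dirichlet hyperparameter

`alpha` is never re-estimated. It is set by policy: a fixed symmetric
value, or the logistic schedule
`alpha(K) = c1 + 1/(1 + exp(c2 (K - V/2)))` (defaults `c1 = 0.3`,
`c2 = 0.25`) which starts near `c1 + 1` for small topic counts and decays
towards `c1` once `K` exceeds half the vocabulary size — a smooth
alternative to the classical `50/K` rule that never drops below a fixed
floor. `alpha_curve()` exposes the schedule; it is exactly `c1 + 0.5` at
`K = V/2` and monotone decreasing in `K` for positive `c2`.

## What the generator emulates — and what it does not

`synthetic_spec()` / `sample_corpus()` sample labeled corpora from the
model's own generative process, so every stage of the pipeline is testable
without patient data. Three presets fix the study conditions:

* `tiny` — unit-test scale: `K = 3`, 4 features over 10 values, `D = 60`,
  5-10 tokens per document, 3 classes.
* `separable` — the classification and recovery testbed: `K = 3`,
  5 features over 15 values, `D = 300`, 20-40 tokens, 3 classes, and
  orthogonalized class coefficients scaled by `eta_scale = 30`. The scale
  was chosen once so that classifying from the *true* topic frequencies
  agrees with the sampled labels about 97% of the time: the softmax
  response is stochastic, so label noise — not estimation error — caps
  achievable accuracy, and a "well-separated" preset must put that cap
  well above the 90% the experiments demonstrate.
* `chd-like` — mirrors the shape of a coronary-heart-disease
  discharge-record cohort: `D = 420`, 34 features owning 79 values in
  blocks of 2-3, 25-34 tokens per document, 4 classes with prior
  `(0.631, 0.233, 0.029, 0.107)`.

Class imbalance is injected by adding `log(class_prior)` to the softmax
scores; with a uniform prior this is exactly the model's GLM, and with
`eta_scale = 0` label frequencies reproduce the prior. Class-coefficient
rows are drawn as random Gaussian vectors anchored on distinct topics
before orthogonalization, so every class owns a region of the topic
simplex.

What the generator does *not* emulate: missing data (imputation is an
upstream hook by design), correlated features, annotator noise, free-text
variability, and covariate shift between cohorts. Passing tests therefore
demonstrate correctness of the inference machinery and sane behavior under
the model's own assumptions — not clinical validity on real records.

## Experiment protocols (sizes used by the test suite)

* *Bound vs evidence*: 200 random instances with `N <= 4`, `K <= 3`,
  `F <= 2`, `C <= 3`, where `K^N` enumeration of the exact evidence is
  feasible; the converged bound must never exceed it.
* *Recovery*: corpora of `D = 100` and `D = 500` documents from a known
  `separable` generator; fits use `n_init = 3`, `em_rel_tol = 1e-5`. The
  permutation-aligned mean total-variation error of `(pi, beta)` must fall
  below 0.15 at `D = 500` and decrease with `D`.
* *Classification*: stratified 5-fold cross-validation on the `separable`
  preset (`D = 300`), `n_init = 3`; mean accuracy must reach 90%.
* *Monotonicity*: ten seeded fits on `tiny`, with per-document and
  corpus-level traces checked at `1e-6` relative slack.

These sizes are the package's chosen study conditions; the same
experiments scale up unchanged.

## Numerical choices

* All softmax/normalizer arithmetic is in log space with log-sum-exp.
* `phi` is initialized uniform, `gamma` at `alpha + W/K`, `eta` at zero;
  `pi`/`beta` start from flat Dirichlet draws under a seed derived from
  the configuration seed, so runs are exactly reproducible.
* E-steps inside EM warm-start from the previous iteration's state;
  prediction-time E-steps start cold.
* Tolerances: per-document bound change `1e-6` (at most 100 sweeps), EM
  relative change `1e-4` (at most 100 iterations), CG gradient
  infinity-norm `1e-5` (at most 500 iterations).
* Prediction ties break toward the lowest class index; zero-token
  documents get the uniform topic mixture, a flag, and the convention
  `rbar = 0` (uniform class probabilities) wherever a response term is
  needed.
* Corpus files store weights with 17 significant digits, and model JSON
  stores all matrices the same way, so write/read round trips are
  bit-stable.

## Design decisions that were genuinely open

* **Block-normalized `beta`.** The value multinomials are normalized
  within each `(topic, feature)` block, matching the generative draw
  `v_n ~ Mult(beta[r_n, block(f_n)])`. A per-topic global normalization
  would double-count feature frequency already carried by `pi`.
* **Risk tiers are a reconstruction.** `risk_factor_table()` ranks topics
  per class by `eta[c, k]`, takes the top/bottom `top_topics` as the
  high/low tier, and scores values by the tier's softplus-weighted
  generative mass `sum_k w_k beta[k, v] pi[k, feature(v)]`. This is one
  defensible reading of "top risk factors per tier"; no canonical
  definition exists.
* **SMOTE placement.** Balancing is done on the training fold only by
  default (no leakage into test folds); a `smote_in_fold = FALSE` switch
  reproduces protocols that balance the whole corpus before splitting and
  report balanced totals. Interpolation happens in the dense per-document
  weight space actually fed to the model, with `k = 5` neighbors and
  Euclidean distance.
* **Macro-F1** is the mean of per-class F1 scores (the common convention),
  not the harmonic mean of macro-precision and macro-recall.
* **Stratified folds.** Plain k-fold on a cohort where one class holds 3%
  of documents can lose that class from training folds entirely;
  stratification is the default and the only mode exposed.

## Known limitations

* Training cost is `O(D * N * K * C)` per EM sweep. The labeled token
  sweep and the response objective run in compiled code; everything else
  is R. Corpora in the tens of thousands of documents will still want
  smaller `K` or patience.
* The `eta` objective is concave only for fixed responsibilities; the
  overall EM still converges to a local optimum, hence the restart
  machinery.
* `alpha` is policy-set, never estimated; if the schedule's constants are
  wrong for a corpus, the model cannot correct them from data.
* The risk-tier construction is descriptive, not causal; tier membership
  reflects the fitted coefficients, and on small cohorts those have
  substantial variance.
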