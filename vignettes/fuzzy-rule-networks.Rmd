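---
title: "Fuzzy rule networks with tropical smoothing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy rule networks with tropical smoothing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzznet)
```

## The model

`fuzznet` fits an interpretable rule-based classifier for tabular clinical
risk prediction. The network has three layers, and every trained quantity
has a direct clinical reading.

**Encoding layer.** Each continuous measurement $x_i$ (standardized) is
mapped to degrees of membership in three fuzzy concepts — *low*, *medium*,
*high* — by smoothed trapezoids built from the smoothed hinge
$f_\varepsilon(x) = \varepsilon \log(1 + e^{x/\varepsilon})$:

$$
l(x) = f_\varepsilon\!\Big(\tfrac{a_2 - x}{a_2 - a_1}\Big) -
       f_\varepsilon\!\Big(\tfrac{a_1 - x}{a_2 - a_1}\Big), \qquad
h(x) = f_\varepsilon\!\Big(\tfrac{x - a_3}{a_4 - a_3}\Big) -
       f_\varepsilon\!\Big(\tfrac{x - a_4}{a_4 - a_3}\Big),
$$

with $m(x)$ the analogous four-term combination minus one. The four
cutoffs $a_1 \le a_2 \le a_3 \le a_4$ are *learned from the data*, not
pre-specified, which is the basis for the range-inference output. A useful
identity: because $f_\varepsilon(z) - f_\varepsilon(-z) = z$, the three
degrees sum to exactly 1 for every $\varepsilon$, not only in the crisp
limit (the test suite asserts this at machine precision). Binary
comorbidities skip membership functions entirely: their levels
(absent/present) act as concepts directly.

**Rule layer.** Rule $k$ attends to concepts through an attention tensor
$A \in [0,1]^{N \times D \times K}$
($\tilde x_{i,k} = \sum_d A_{i,d,k}\, z_{i,d}$) and weights whole features
through a connection matrix $M \in [0,1]^{N \times K}$ used as exponents in
a parameterized T-norm:

$$
r_k = \Big(\sum_{i=1}^{N} \tilde x_{i,k}^{\,M_{i,k}\frac{\varepsilon - 1}{\varepsilon}}
      - N + 1\Big)^{\frac{\varepsilon}{\varepsilon - 1}} .
$$

As $\varepsilon \to 1$ this is the product of the attended degrees (a
probabilistic AND); as $\varepsilon \to 0$ it degenerates to their minimum
— the tropical (min-plus) limit, i.e. crisp rule logic. An exponent
$M_{i,k} = 0$ removes feature $i$ from rule $k$ entirely.

**Inference layer.** Class scores combine rule firings through a
parameterized T-conorm,
$O_c = \big(\sum_k (W_{k,c}\, r_k)^{1/\varepsilon}\big)^{\varepsilon}$,
which interpolates between a sum ($\varepsilon \to 1$) and a maximum
($\varepsilon \to 0$); $W_{k,c} \ge 0$ is the contribution of rule $k$ to
class $c$. Class probabilities are the softmax of $O$. The scores are
unbounded above (in the additive regime they are sums of weighted
firings), so a bare normalization would be unstable; softmax also pairs
naturally with the weighted cross-entropy loss.

## Numerical choices

* **Log-space operators.** Late in training $\varepsilon$ is small and the
  T-norm exponent $(\varepsilon - 1)/\varepsilon$ reaches magnitudes near
  $1/\varepsilon_{min} \approx 100$; direct powers of clamped inputs
  ($10^{-6}$) overflow double precision by hundreds of orders of
  magnitude. Both operators are therefore evaluated with log-sum-exp
  identities. The naive direct formulas survive as independent oracles in
  the tests at moderate $\varepsilon$.
* **Input clamping.** Conjunction inputs are clamped to
  $[10^{-6}, 1]$ before exponentiation. With inputs $\le 1$ and
  nonpositive exponents every weighted term is $\ge 1$, so the inner sum
  $\sum_i u_i - N + 1$ is mathematically $\ge 1$ and never needs rescue
  clipping; a hard floor is kept as an inert guard. (An earlier design
  sketch smoothed this floor with the hinge at the current $\varepsilon$;
  that distorts the operator by several percent at moderate smoothness and
  was dropped.)
* **Parameter constraints by reparameterization.** $A$ and $M$ live behind
  sigmoids, $W$ behind a softplus, and cutoffs are a free $a_1$ plus three
  softplus gaps floored at $10^{-3}$ (the membership denominators
  $a_2 - a_1$ and $a_4 - a_3$ can therefore never vanish). Gradients stay
  smooth everywhere, unlike hard projection.
* **Smoothness schedule.** One shared $\varepsilon$ drives all three
  layers (per-role overrides exist in the network object). It starts at
  0.99 — the product/sum regime where gradients flow through every input —
  and decays by $\gamma = 0.999$ per optimizer step to a floor of 0.01,
  annealing the network toward crisp min/max rule logic. $\varepsilon$ is
  scheduled, never trained.
* **Gradients.** No autodiff framework is used: backpropagation through
  memberships, both operators, softmax cross-entropy, the penalties and
  all reparameterizations is analytic, and is verified against central
  finite differences (relative error $< 10^{-4}$ for every parameter
  group) in the test suite.

## Training

The loss is weighted cross-entropy (class weights default to inverse
class frequency, upweighting the rarer positive class) plus
$\lambda_1 (\lVert \mathrm{vec}\,A \rVert_1 + \lVert \mathrm{vec}\,M \rVert_1)$
for term sparsity and
$\lambda_2 \sum_{j<k} \langle \mathrm{vec}\, S_{:,:,j},
\mathrm{vec}\, S_{:,:,k} \rangle$ for rule decorrelation, where
$S_{i,d,k} = A_{i,d,k} M_{i,k}$ is the contribution matrix. Optimization
is Adam (defaults: learning rate 0.01, 200 epochs, batch 64,
$\lambda_1 = \lambda_2 = 10^{-3}$; all searchable through
`random_search()`). The weighted cross-entropy is normalized by the sum of
sample weights so its scale does not drift with the class-weight
magnitude. Cross-entropy, when the batch is uniform and unweighted,
reduces to the ordinary mean log loss, which the tests assert to
$10^{-10}$.

Defaults that the underlying method leaves open (optimizer
hyperparameters, $\lambda$s, extraction thresholds below) are package
choices, exposed in `train_config()` and function arguments rather than
hard-coded.

## Rules in and rules out

`init_from_rules()` maps a symbolic rule set onto the first rule columns:
attention at each (feature, concept) term is set to the term importance
(0.9 for expert rules), connection weights of the rule's features to 0.9,
the positive-class inference weight to 0.9, and everything else to 0.05 —
enough to bias training without pinning it. Remaining columns keep small
random seeded values, and cutoffs start at marginal data quantiles
(10/35/65/90%). `hf_referral_rules()` ships the four advanced
heart-failure referral rules used as the clinical prior (low LVEF combined
with low SBP, severe mitral regurgitation, rising BNP, or hyponatremia).

`extract_rules()` inverts the map after training: rule strength is the
*mean firing over a reference dataset* (robust to outliers, unlike the
max), rules below a strength threshold (default 0.1) are dropped, highly
correlated survivors are pruned greedily by cosine similarity of their
contribution columns (default threshold 0.9; cosine, not the raw inner
product of the training penalty, because pruning needs a scale-free
score), and terms are kept where $S_{i,d,k} \ge 0.2$. By default only
rules whose dominant inference weight points at the positive class are
reported: a clinical referral rule set contains referral rules. For
cross-fold ensembling, however, `run_cv()` extracts rules of *every*
class, because re-initializing the final network only with positive rules
would discard the learned protective (negative-class) decision structure.
`ensemble_rules()` pools fold rule sets,
keeps the strongest mutually decorrelated rules, and is idempotent.

Each extracted rule reports two contribution numbers — mean firing
strength and its inference-weight row — because either is a defensible
summary of a rule's importance; neither is claimed to be canonical.

## Range inference and explanations

`critical_values()` reports, per continuous feature, the points where each
membership ramp crosses 0.5 (low boundary, medium left/right, high
boundary), solved by bisection to $10^{-6}$ standardized units inside a
bracket spanning the cutoffs $\pm$ half their span, then mapped back to
clinical units with the stored standardization statistics. With near-crisp
memberships the 0.5-crossing coincides with the intersection of adjacent
membership curves; the 0.5 convention remains well defined when the curves
do not intersect cleanly, and the output records the convention
explicitly. Degenerate ramps that never bracket 0.5 are omitted with a
warning rather than silently extrapolated.

`explain_sample()` returns, for one preprocessed row, the class
probabilities plus the top rules by firing strength with per-term
membership degrees; strengths are bit-identical to `rule_strengths()` on
the same row.

## The cohort pipeline

The preprocessing mirrors longitudinal EHR practice: consecutive
hospitalization pairs per patient (features from the first encounter,
label from the second), derived features (MAP as $DBP + (SBP - DBP)/3$,
the standard clinical estimate; pulse pressure; percent changes of BNP and
creatinine over the hospitalization with a zero first measurement masked,
never divided), missingness filters (features over 60% missing are
dropped unless echo-exempt; patients with more than ten missing cells are
excluded), carry-forward imputation within patient followed by a seeded
chained-equations-style stochastic completion (a single completion is
used for model input, since nothing downstream pools multiple draws),
z-scoring with statistics fit on training rows only, and patient-wise
stratified splitting (a patient is positive if any pair is positive; all
of a patient's pairs follow the patient). Leakage is guarded by assertion
hooks: imputation and standardization record the rows they were fit on
and the drivers verify those are training rows.

## The synthetic cohort generator

Real referral cohorts are protected health data, so validation runs on a
generator that emulates one at realistic scale: 300 patients whose
encounter counts follow the reported distribution (52% two encounters,
22% three, the rest more), vitals/labs/echo measures with
clinically plausible means and spreads, within-patient correlation 0.5,
binary comorbidity flags, heavier missingness on echo measures (20–30%
versus 5%), and eligibility-truncated age (18–80), LVEF ($\le 35$) and BMI
($\le 50$) — a cohort *selected* on those criteria satisfies them by
construction. Labels are the OR of two planted conjunctive rules (SBP
$< 100$ mmHg $\wedge$ LVEF $< 23\%$; LVEF $< 23\%$ $\wedge$ sodium
$< 136$ mmol/L) evaluated on the first encounter of each pair, flipped
with 10% noise; the thresholds were calibrated analytically, once, so the
post-noise positive rate is $\approx 35\%$ ($0.8 p + 0.1 \approx 0.35$
for a pre-noise rate $p \approx 0.31$).

What passing on this generator shows — and what it does not: recovery of
planted conjunctions demonstrates that the estimator inverts its own
generative family (crisp conjunctions under flip noise, Gaussian-ish
marginals, MCAR missingness). Real EHR data have informative missingness,
drifting measurement conventions, label leakage hazards and non-crisp
risk structure; performance there is an empirical question the synthetic
experiments cannot answer.

## Problem sizes and determinism

The shipped experiments use the full 300-patient cohort for the
five-fold + holdout protocol, 500-sample single-feature experiments for
range inversion, and a 5-feature/3-rule/2-class instance for the
finite-difference gradient audit. Every stochastic step — generation,
folds, imputation draws, initialization, minibatch order — derives from
one master seed; two runs with the same seed are bit-identical, which the
tests assert on the protocol end to end.

## Known limitations

* One rule layer and single-label outputs only; no more than three
  concepts per continuous feature.
* Rule strength thresholds interact with prevalence: a genuinely rare
  conjunction can sit near the default 0.1 mean-firing threshold (the
  thresholds are arguments for this reason).
* The chained imputation uses linear models; strongly nonlinear
  missingness mechanisms are out of scope.
* Categorical features with many levels consume attention slots up to the
  maximum level count; very high-cardinality categoricals should be
  grouped before modeling.
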