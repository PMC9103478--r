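---
title: "Methods: an additive neural classifier for uric acid nephrolithiasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an additive neural classifier for uric acid nephrolithiasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Uric acid stones account for roughly 10–15% of urinary stones and, unlike
calcium-based stones, can often be dissolved by oral chemolysis instead of
surgery. Composition, however, is normally confirmed only after retrieval.
`uastone` implements a pre-treatment classifier over eight variables
obtainable at the first visit — sex, age, eGFR, urine pH, BMI, and history
flags for diabetes mellitus, gout and bacteriuria — that outputs the
probability that a patient's stone is pure uric acid.

## Model

The score is additive over per-feature subnetworks:

$$f(x) = \sum_{i=1}^{5} a_i f_i(x_i) + a_6 f_6(x_6, x_7, x_8) + b,$$

where each $f_i$ is a fully connected two-layer network with hidden width
$h$ (default 20): a first layer *without bias terms*, a scalar output with
bias $B_{i,2}$, i.e. $f_i(x_i) = \sigma_{i,2}(A_{i,2}\,\sigma_{i,1}(A_{i,1}
x_i) + B_{i,2})$, and the sixth subnetwork pools the three binary flags
through a shared hidden layer. The parameter count is therefore
$5(2h{+}1) + (4h{+}1) + 7 = 14h + 13$, i.e. 293 at $h = 20$; the absence of
first-layer biases is forced by that count, not a stylistic choice. The
output probability uses

$$y = \frac{1}{1 + e^{f(x)}},$$

which is *decreasing* in $f$. We keep this orientation verbatim: training
simply learns negatively signed scores for the uric acid class, and all
evaluation ranks patients by $y$ (probability of uric acid), so cutoffs live
on the familiar $(0,1)$ probability scale. A `probability = "sigmoid"`
configuration flag provides the conventional orientation for comparison.

The activation functions are not pinned down by the design beyond being
standard; we default to ReLU hidden layers and a tanh output (bounding each
term's contribution to $[-|a_i|, |a_i|]$, which keeps the additive
decomposition readable), and both are configurable. Exact replication of any
particular historical fit is therefore not attempted — the architecture,
loss and evaluation protocol are what the package reproduces.

Interpretability follows from additivity: `feature_contributions()` returns
the exact decomposition $a_i f_i$ (summing to $f(x)$ to $10^{-10}$), and
`autoplot()` on a fitted model draws the learned shape functions.

## Feature encoding and scaling

Features enter in the fixed order sex, age, eGFR, urine pH, BMI, DM, gout,
bacteriuria. When eGFR is absent but serum creatinine is supplied, eGFR is
computed by the IDMS-traceable MDRD equation
$175 \cdot \mathrm{Scr}^{-1.154} \cdot \mathrm{Age}^{-0.203} \cdot
0.742^{[\text{female}]}$. Records with missing fields are rejected outright —
the study population excluded patients without detailed records, and silent
imputation would change the estimand.

The four numeric features are standardized by training-set z-scores
(population SD); binaries enter raw. Whether the original analysis scaled
its inputs is not stated anywhere; we standardize because raw inputs
spanning $[0, 120]$ against $\{0, 1\}$ make bias-free first layers nearly
untrainable, and an affine reparameterization of each input leaves the model
family unchanged. The scaler is fitted on the training split only and reused
frozen on all validation and external data.

## Synthetic cohorts

The study data are not publicly deposited, so the generator emulates the two
cohorts from their published class-conditional marginals:

* **Cohort A**: 146 pure uric acid / 952 other. Uric acid group numerics
  (mean, SD): age (60.44, 12.52), BMI (25.63, 3.80), urine pH (5.51, 0.54),
  eGFR (55.13, 29.45); non-uric-acid: age (52.75, 12.69), BMI (25.38, 3.53),
  pH (6.09, 0.77), eGFR (80.14, 29.37). Binary proportions pool the
  training and validation columns of the published descriptive table
  (e.g. male 110/146 vs 638/952), since the 60/40 split happens downstream
  of generation.
* **Cohort B**: 3 / 68, with the uric acid group all male and urine pH
  degenerate at 5.0 (printed SD 0).

Numerics are drawn from truncated normals whose *parent* parameters are the
printed means/SDs, with physiologic bounds age [18, 95], BMI [14, 50], pH
[4.5, 8], eGFR [2, 180] (the source is silent on ranges; these keep values
clinically plausible). The moment-recovery tests therefore compare against
truncation-corrected expectations computed in closed form and verified
against numeric integration; at these parameters the corrections are small
(the largest, uric acid eGFR near its lower bound, shifts the mean by a few
percent; the pH correction is +0.04).

Within a class, features are drawn independently — only marginals are
published, so independence is the maximum-entropy default. A Gaussian-copula
hook accepts a Spearman rank-correlation matrix for sensitivity experiments
without changing any marginal. Group sizes are exact, never sampled, so the
146/952 and 3/68 compositions (13.3% and 4.2% prevalence) hold for every
seed. Age is generated continuously; the published age bands (≤45, 45–65,
>65) are exposed only as a descriptive report (`cohort_summary()`).

What passing tests on these cohorts shows — and does not show: the generator
reproduces the first two class-conditional moments and the class balance,
which is what drives separability (eGFR and pH differ by ~0.8 SD between
classes), but it cannot reproduce the real data's joint structure, outliers,
or measurement artifacts. Training results on synthetic cohorts demonstrate
that the pipeline works and that the published effect sizes imply learnable
separation; they do not re-validate the clinical model.

## Splitting and training

`split_cohort()` assigns `floor(0.6 n)` records to training (658/440 at
n = 1098, matching the published split sizes); the default draw is a simple
random partition, matching the protocol's wording, with a stratified option.

Training minimizes class-weighted binary cross-entropy; weights default to
inverse-prevalence balancing $w_+ = n/2n_+$, $w_- = n/2n_-$ (under which the
best constant predictor is 0.5 regardless of imbalance). The optimizer and
schedule are unreported in the source protocol, so the package uses
conventional choices, all configurable: Adam at learning rate $10^{-3}$,
batch size 32, at most 500 epochs, early stopping on validation loss with
patience 25, returning the best-validation snapshot. Gradients are
hand-derived backpropagation through the six subnetworks (293 parameters do
not warrant an autodiff framework) and are tested against central finite
differences at relative error $<10^{-4}$. Predictions are clipped at
$\varepsilon = 10^{-7}$ inside the loss; gradients use the unclipped
sigmoid. Divergence (non-finite loss or parameters) aborts with the epoch in
the message. All randomness — initialization (zero-mean normals scaled by
$1/\sqrt{\text{fan-in}}$; output biases 0; $a_i, b$ small nonzero) and
shuffling — derives from one master seed.

## Evaluation

ROC analysis treats $y$ (probability of uric acid) as the ranking score and
uses the inclusive rule score ≥ cutoff. The AUC is the trapezoidal area and
is tested to coincide with the Mann–Whitney statistic (ties ½) to
$10^{-12}$; these are two independently coded routes. The operating point
maximizes Youden's $J$ over midpoints between adjacent distinct scores; ties
are broken toward the smallest cutoff, favoring sensitivity — the preferable
error direction for a rule-out-surgery screen. For all-equal scores the
degenerate answer is $J = 0$ at the single observed value.

Proportion intervals are Wald $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$,
clipped to $[0,1]$ — this is the construction that reproduces the published
intervals exactly from the reconstructed confusion counts (e.g. sensitivity
50/59 → 0.756–0.939); Wilson intervals are available by flag and behave
better at $\hat p$ near 0 or 1. AUC intervals default to DeLong (tested
against pROC), with a seeded stratified bootstrap alternative. Metrics with
zero denominators are reported as undefined (`NA`), never 0. The
random-guess baseline (50% sensitivity/specificity) collapses to PPV =
prevalence, NPV = 1 − prevalence.

The pipeline mirrors the three published evaluations: the Cohort A
validation split at its own Youden cutoff, Cohort B at its own Youden
cutoff, and Cohort B at the Cohort-A cutoff.

## Reproducibility surface and limitations

The published AUCs (0.842 validation / 0.936 external) and cutoffs
(0.470 / 0.688) depend on the non-deposited patient data and unreported
hyperparameters, so they are not exact targets. The suite instead checks the
properties the published tables *do* determine: the 293-parameter structure;
every printed rate and Wald interval as an identity of the reconstructed
confusion counts; the random-guess baselines; generator composition and
moment recovery (3 standard errors at n-scale 100); dual-route agreement of
AUC, Youden search and gradients; and that training on synthetic Cohort A
(5 seeds, default generator) reaches median validation AUC ≥ 0.75 — on the
synthetic cohorts the default configuration typically lands near 0.84,
consistent with the class separation implied by the published moments.

Problem sizes used by the checks (chosen as comfortable Monte-Carlo scales):
moment recovery at $10^5$ per group and n-scale 100 for the mean checks;
1000 random instances (n ≤ 30) for the oracle equivalences; five training
seeds at the study's own n = 1098.

Known limitations: independence within class is an idealization; truncated
parent-parameter interpretation shifts means slightly near bounds; Wald
intervals degenerate at $\hat p \in \{0, 1\}$ (kept as default for fidelity
to the published intervals); the degenerate pH of the three external uric
acid patients makes external metrics fragile to a single patient; and the
activation choice means fitted shape functions are comparable across runs of
this package, not to the original fit.
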