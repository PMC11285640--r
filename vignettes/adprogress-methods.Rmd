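---
title: "Methods: causal weighting, neural and ensemble prediction of MDD-to-AD progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal weighting, neural and ensemble prediction of MDD-to-AD progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depression is a well-documented precursor of Alzheimer's disease (AD).
In longitudinal medical-claims data, patients with major depressive
disorder (MDD) can be followed over years of ICD-coded diagnoses, and
one can ask which of them will later accrue an AD diagnosis. Two
obstacles make this harder than ordinary supervised learning. First,
yearly MDD-related care (the "exposure") is entangled with time-varying
illness burden that also drives progression — classic time-varying
confounding, which biases any regression that simply adjusts for
measured covariates. Second, the signal is partly non-linear and
interaction-shaped, which linear models miss.

`adprogress` addresses both with a stacked design:

1. a **marginal structural model (MSM)** — a linear probability model
   fitted by weighted least squares, whose observation weights are
   **stabilized inverse-probability-of-treatment weights (IPTW)** so its
   coefficients estimate marginal associations under the weighting
   assumptions;
2. a **multilayer perceptron (MLP)** — one hidden ReLU layer trained
   with L-BFGS — to capture non-linear structure;
3. an **integrated predictive model (IPM)**: a gradient-boosted
   classifier whose only inputs are the two base probabilities
   `[pANN, pMSM]`.

## Weighting model

For patient $i$ with yearly exposure indicators $E_t$
($t = 0, \dots, T$, year resolution, $t=0$ the first window year),
baseline covariates $X_0$ and lagged time-varying covariates $X_{t-1}$,
the stabilized weight is

$$
SW_i \;=\; \prod_{t=0}^{T}
\frac{P(E_t \mid E_{t-1}, X_0)}{P(E_t \mid E_{t-1}, X_0, X_{t-1})},
$$

with the probability of the exposure *actually received* ($p$ if
$E_t = 1$, $1-p$ otherwise) entering numerator and denominator alike,
and the $E_{t-1}$, $X_{t-1}$ terms dropped at $t = 0$ (the baseline
terms then cancel exactly). Both conditional probabilities come from
pooled logistic regressions with year fixed effects.

Two conventions deserve comment:

* **The numerator conditions on $X_0$.** That is the form the weighting
  equation states in the source methodology this package follows; the
  textbook stabilized numerator conditions on exposure history only.
  `fit_exposure_models(stabilizer = "conventional")` switches to the
  textbook form. A consequence of the printed form is that baseline
  covariates appear in numerator and denominator alike and are therefore
  *not* balanced by the weights — only time-varying confounding is
  addressed. The bundled simulator mirrors this: demographics influence
  the outcome but deliberately not the exposure process.
* **The denominator conditions on $X_{t-1}$, not $X_t$** — the printed
  lag convention, kept as is.

Numerical choices: degenerate years (every patient identically exposed)
contribute probability 1 to both products; realized denominator
probabilities are floored at `1e-6` (count reported); perfect separation
falls back to a small ridge penalty with a warning. Weight truncation
beyond the floor is off by default because the source protocol specifies
none.

The exposure–outcome regression is a linear probability model (weighted
least squares with HC1 robust standard errors), so predictions are
clipped to $[0,1]$. Aliased columns are dropped with a warning.

## Base learner: the MLP

Hyperparameters are fixed at the selected values of the original
grid search: ReLU activation, L-BFGS solver, L2 penalty
$\alpha = 10^{-8}$, tolerance $10^{-3}$, one hidden layer of 6 units,
at most 1,200 iterations, random state 4. "Hidden layers of 6" is read
as one layer of six units, consistent with a scalar layer-size
specification and the single-hidden-layer schematic of the source
architecture; a deeper `hidden_layer_spec` remains available. The
`learning_rate_init` field is retained for the record but is not
consumed by a quasi-Newton solver. The network is trained on z-scored
features (training statistics only); initialization is Glorot-uniform
under the fixed random state, so fits are bit-identical.

Feature importance is the sum of absolute first-layer weights per input,
with a one-sample t-test of the signed weights against zero. With six
weights per feature the test has little power; it is reported because it
is the protocol's significance device, not because it is a good one.

## Encoding: one column per predictor

All nine predictors (age band, gender, race, rural–urban, HPSA class,
comorbidity, follow-up, utilization days, MDD claim count) enter as a
single numeric column each — integer level codes for the categorical
ones, in the natural order for the ordered ones (age, HPSA). The
reporting convention this package mirrors shows exactly one MSM
coefficient and one MLP weight-sum per predictor, which is only possible
under a single-column encoding. One-hot encoding would change the
feature-ranking semantics and is intentionally not the default.

## The ensemble and its stacking mode

The meta-learner is gradient-boosted trees (100 rounds, learning rate
0.01, depth 3, 60% row subsample per round drawn without replacement,
random state 28) on the two base probabilities. The decision that was
genuinely open is *which* base probabilities the meta-learner trains on:

* **In-sample** (`cross_fit = FALSE`): base models predict their own
  training rows. Implementation experience showed a systematic failure
  mode: the MLP's in-sample probabilities are optimistically separated,
  the booster learns to trust them, and the ensemble's held-out AUC
  falls below the better base model.
* **Cross-fitted** (default): 5-fold out-of-fold base predictions,
  computed entirely within the training partition — so every model still
  uses the same training data — give the meta-learner honestly
  calibrated inputs. This is classic stacked generalization, and it
  keeps the ensemble tracking the better base model closely.

Even cross-fitted, a flexible tree meta-learner pays a small price at
this sample size: on the bundled simulator's case-control design
(452 training rows) the boosted stack averages within about one AUC
point of the better base model rather than strictly above it, because
the booster partly fits out-of-fold noise in its two-column input. A
plain average of the two base probabilities is slightly better than
either base there; the boosted meta-learner is retained because it is
the specified combiner and dominates the weaker base by a wide margin.

Prediction is end-to-end: callers pass raw encoded predictor rows, never
stack features. Weights matter for fitting the MSM only; prediction
needs none. The classification threshold (0.5) is configurable because
the source protocol never states one.

## Synthetic claims simulator

No real Medicare extract can ship with a package, so every stage is
exercised on a seeded generative model of the study design:

* two arms (progressed to AD vs remained MDD) drawn by rejection from a
  discrete-time structural model over an 8-year window (2012–2019),
  ICD-9 codes through 2015 and ICD-10 from 2016;
* a latent illness-burden process $Z_t$ (AR(1) plus a feedback term from
  past exposure) that drives yearly MDD-coded care, comorbidity claims
  and utilization days — the time-varying confounder;
* a yearly progression hazard (logistic) depending on cumulative
  exposure, current burden, a standard-normal latent factor $U$ that
  enters the outcome only (unmeasured confounding stand-in), and a
  baseline interaction term — the XOR of older age (75+) and urban
  residence — that is invisible to a main-effects linear model but
  learnable by the network ("dual signal");
* every progressor's first AD-coded claim strictly after the first
  MDD-coded claim year; controls carry no AD code within the window
  (the control arm is defined as never progressing by the window's end);
* the AD-onset claim carries zero utilization days, so the endpoint
  never leaks into the utilization feature;
* covariate prevalences default to the pooled descriptive margins of the
  emulated study, for face validity of descriptive tables.

Default effect sizes (log-odds scale): confounding strength 0.6 (one
knob scaling both the burden-to-exposure and burden-to-outcome arrows,
so zero removes the confounder entirely), 0.25 per cumulative exposed
year, 0.5 for the latent factor, 1.0 for the XOR term. These were fixed
once as a plausible mid-strength confounding scenario in which weighting
is consequential but positivity is unproblematic.

Two switches exist purely for estimation studies: `mode = "population"`
draws patients without outcome-conditioned selection (case-control
selection would itself bias marginal-effect estimates), and
`intervene = TRUE` removes the burden term from the exposure equation
while leaving all outcome equations untouched — the unconfounded regime
whose regression slope serves as the ground truth in parameter-recovery
experiments.

What the simulator does *not* emulate: enrollment gaps and censoring,
billing semantics, sub-year claim dating, code sets beyond the
MDD/AD/comorbidity families used here, and measured-covariate
missingness mechanisms other than MCAR. Passing tests therefore show
that the pipeline is correct and directionally well-behaved under the
assumed mechanism — not that real claims data would yield the same
metric levels.

## Cohort construction rules

MDD is the 296.2X (ICD-9) / F32.X (ICD-10) family by prefix match; AD is
331.0 / G30.0, G30.1, G30.8, G30.9 by exact match. The recurrent
families (296.3X, F33.X) are excluded by default because the printed
code list excludes them, although the surrounding text mentions
recurrent depression; `code_registry(extended = TRUE)` adds them
explicitly — the two registries are never merged silently. A patient
progresses if the first MDD year strictly precedes the first AD year;
same-year ties are excluded because precedence cannot be established at
year resolution. "Visits" for the follow-up flag are distinct MDD-coded
claims. Utilization days sum over claims in or after the first MDD year.
Chi-square tests use no continuity correction by default (the common
default for r×c tables); a switch is provided.

## Sensitivity protocol

40% of predictor cells (never the outcome) are masked completely at
random, then multiply imputed (m = 5 by default) by a data-augmentation
Gibbs sampler under a joint multivariate-normal model: posterior draws
of the mean and covariance given the completed data, then conditional
normal draws of the missing cells, 50 warm-up sweeps per independently
seeded chain. Categorical codes are imputed on the continuous scale and
decoded by nearest-level rounding — a known mismatch of the normal
model, accepted as the protocol-faithful compromise; chained-equations
imputation is deliberately out of scope. Models are refitted on each
completed dataset by default ("refit"); a "rescore" mode applies the
already-fitted ensemble instead, since the source description is
ambiguous between the two. Metrics are pooled as per-dataset means; a
single-dataset mode mirrors the protocol's singular phrasing. The
imputation model is fitted on all rows (train and test) of the masked
table, as the distortion protocol operates on the full dataset before
the split is re-applied.

## Problem sizes used in the test suite

The statistical suites run at sizes chosen to give stable Monte-Carlo
averages while remaining desk-scale: the weight-cancellation null at
5,000 patients; parameter recovery over 200 replicates of 2,000-patient
population draws against a 100,000-patient counterfactual truth; the
stacking and sensitivity direction properties over 50 replicates of the
564-patient case-control design (the emulated study's size), with one
fresh distortion-imputation draw per replicate — the direction is
estimated across replicates, so multiple imputations per replicate would
only smooth within-replicate noise. End-to-end determinism runs the full
pipeline twice at 100 patients.

## Known limitations

* The printed-numerator weight form leaves baseline confounding to the
  outcome model (see above).
* The linear probability MSM can predict outside $[0,1]$ before
  clipping, and its coefficients are scale-bound to the integer level
  codes.
* The MLP significance test treats six weights as a sample.
* Bootstrap AUC intervals (2,000 stratified percentile resamples by
  default; a DeLong-type asymptotic interval is available) are reported
  per completed dataset and averaged under multiple imputation, which
  understates between-imputation variance.
* No censoring weights: the emulated protocol fits none, and the
  simulator generates complete follow-up.
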