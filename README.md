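# adprogress

Predicting progression from major depressive disorder (MDD) to
Alzheimer's disease (AD) in longitudinal claims data, for
epidemiologists and clinical data scientists who want causal structure
*and* machine-learning flexibility in one pipeline.

## The model

Patients with ICD-coded depression (296.2X / F32.X) are followed over an
8-year window for a first AD-coded claim (331.0 / G30.0–G30.9) that must
strictly follow the first MDD claim. Yearly MDD-related care is a
time-dependent exposure confounded by evolving illness burden, so a
plain regression is biased. The package combines:

1. **Stabilized IPTW.** For yearly exposure indicators E_t with baseline
   covariates X_0 and lagged time-varying covariates X_{t-1},

   ```
   SW = prod_{t=0..T}  P(E_t | E_{t-1}, X_0)
                      ---------------------------------
                       P(E_t | E_{t-1}, X_0, X_{t-1})
   ```

   estimated by pooled logistic regressions with year fixed effects,
   using the probability of the exposure actually received in both
   numerator and denominator.

2. **Marginal structural model (MSM).** A linear probability model of
   the binary progression outcome on nine predictors (age band, gender,
   race, rural–urban, HPSA shortage class, comorbidity, follow-up,
   utilization days, MDD claim count), fitted by weighted least squares
   with the stabilized weights and HC1 robust errors. Its clipped linear
   predictor is `pMSM`.

3. **Multilayer perceptron.** One hidden ReLU layer of 6 units trained
   by L-BFGS (alpha 1e-8, tol 1e-3, max 1,200 iterations, random
   state 4) on z-scored features; its probability is `pANN`.

4. **Integrated predictive model (IPM).** A gradient-boosted classifier
   (100 rounds, learning rate 0.01, depth 3, 60% subsample without
   replacement, random state 28) stacked on `[pANN, pMSM]`, with
   cross-fitted stack features inside the training partition.

Everything runs on a bundled, seeded synthetic claims simulator that
realizes the assumed causal diagram (time-varying confounding, a latent
outcome-only factor, an interaction signal invisible to linear models),
so no restricted data are needed. A 40%-masking + multivariate-normal
multiple-imputation sensitivity protocol re-evaluates the ensemble
against an MLP-only model.

## Worked example

```r
library(adprogress)

config <- run_config(
  seed = 1,
  simulation = sim_config(n_per_group = 282),   # 564-patient case-control design
  imputation = imputation_config(m = 5)
)
run <- run_pipeline(config)
print(run)
```

```
Pipeline run: 564 patients (452 train / 112 test), master seed 1

Model performance by outcome class
 model         class precision recall   f1 accuracy
   MSM  remained_MDD      0.55   0.61 0.58     0.55
   MSM progressed_AD      0.56   0.50 0.53     0.55
   MLP  remained_MDD      0.52   0.61 0.56     0.52
   MLP progressed_AD      0.52   0.43 0.47     0.52
   IPM  remained_MDD      0.57   0.57 0.57     0.57
   IPM progressed_AD      0.57   0.57 0.57     0.57

AUC (clinical relevance above 0.80)
 model  auc ci_lower ci_upper clinically_relevant
   MSM 0.62     0.51     0.72               FALSE
   MLP 0.61     0.50     0.72               FALSE
   IPM 0.66     0.56     0.75               FALSE

Sensitivity analysis (40% cells masked, 5 imputation(s), refit, per-dataset-mean pooling)

(A) integrated model (MLP and MSM)
         class precision recall   f1
  remained_MDD      0.56   0.61 0.58
 progressed_AD      0.57   0.51 0.54
  accuracy 0.56 | AUC 0.58 (CI: 0.47 - 0.68)

(B) without MSM (MLP only)
         class precision recall   f1
  remained_MDD      0.55   0.56 0.56
 progressed_AD      0.55   0.54 0.54
  accuracy 0.55 | AUC 0.57 (CI: 0.46 - 0.67)
```

Reading the output: each model is evaluated on the 112 held-out
patients. The comparison table mirrors the per-class
precision/recall/F1 layout of clinical prediction reports; the AUC
block flags models crossing the 0.80 clinical-relevance line. In the
sensitivity block, panel (A) keeps the causal (IPTW/MSM) branch and
panel (B) removes it — the drop from (A) to (B) is the measured value
of the causal component once 40% of the predictor cells have been
destroyed and imputed. Exact numbers vary with the master seed; the
ensemble tracks the better base model and the (A) panel stays ahead of
(B) on average across seeds.

Useful pieces on their own:

```r
raw    <- simulate_cohort(sim_config(n_per_group = 282, seed = 1))
cohort <- build_cohort(raw$patients, raw$claims)
descriptive_table(cohort)              # per-arm counts, %, chi-square / t-tests

panel  <- build_panel(raw$patients, raw$claims, 2012, 2019)
w      <- compute_iptw(panel, fit_exposure_models(panel))
print(w)                               # mean weight ~1, extreme-weight share

enc   <- encode_cohort(cohort)
sp    <- split_cohort(enc$outcome, 0.8, seed = 2)
feats <- setdiff(names(enc), c("patient_id", "outcome"))
fit   <- ipm(enc[sp$train, feats], enc$outcome[sp$train],
             weights = w$weight[match(cohort$patient_id[sp$train], w$patient_id)])
coef(fit)                              # MSM coefficients behind the ensemble
predict(fit, enc[sp$test, feats])      # pANN, pMSM, stacked prob, class
```

A thin command-line front end with `simulate`, `build-cohort`, `fit`,
`evaluate`, `sensitivity` and `run-all` subcommands lives at
`inst/scripts/adprogress-cli.R`.

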