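# rollrisk

Self-refreshing disease-risk prediction from real-world clinical tabular
data.

`rollrisk` is for biostatisticians and clinical data scientists who want a
risk calculator that is **built from, and keeps learning from, the local
data system** (an EHR- or claims-like event store) instead of a fixed
published score. Each monthly refresh re-runs the whole pipeline on the
data available at that point: it builds a patient-month time series with a
censored binary outcome, screens tens of thousands of candidate binary
predictors with two empirical retention criteria, encodes the survivors
into historic + contemporaneous indicator schemas, trains a shallow
regularized neural network, and scores the current month's patients. A
rolling pseudo-prospective harness evaluates every refresh the way it
would have been used.

## The statistics at the core

For a patient-month row at month $m$ the outcome is
$y = 1$ iff an endpoint code occurs in months $[m+1, m+L]$ (default
$L = 12$), coded only when the window is observable, with censoring after
the last row before the endpoint month.

Predictor retention, applied per binary predictor (BP) at the patient
level on the analytic dataset:

* **PRC-1** — exact Fisher test on the BP-by-outcome table; retain when
  the two-tailed $p \le \alpha$ ($\alpha = .05$; 2.5% of the sampling
  distribution in each tail — one tail is protective, one is risk). A
  *complete* protective factor (0% carrier outcome rate) can only pass
  once it has at least
  $N_{ProtX\_min} = \lceil \log(\alpha/2)/\log(1-rate) \rceil$
  carriers — 160 at a 2.28% incidence rate, 131 at 2.78%.
* **PRC-2** — risk factors only: with $N$ carriers, $O$ of them
  outcome-bearing, require
  $1 - (1 - O/N)^{\,\mathrm{round}(0.1N)} \ge 0.95$,
  i.e. a random 10% test split should almost surely contain at least one
  outcome-bearing carrier.

The final-stage model is a feed-forward network
(inputs → 32 sigmoid units, L2 $= 10^{-4}$ → 1 sigmoid output) trained
with Adamax on binary cross-entropy in two phases (batch $2^7$, patience
2; then batch $2^{14}$, patience 4, early stopping on test loss with
best-weight restoration). Evaluation reports AUROC, average-precision
AUPRC, PPV and odds ratios for the top-100 and 101–200 patients ranked by
estimated risk, threshold sensitivity/specificity, and per-outcome-group
risk descriptives.

Because real patient data cannot ship with a package, `rollrisk` includes
a synthetic EHR generator (`generate_cohort()`) with planted risk and
protective factors, correlated clinical-journey chains, heavy-tailed null
codes and a known per-month hazard, so every stage is testable and signal
recovery is measurable against the Bayes-optimal score.

## Worked example

The reference synthetic world: 5,000 patients over 48 months, five
planted risk factors (per-month hazard odds multipliers 4–8), two
complete protective factors, 2,000 null codes, ~3% patient-level
incidence. One full refresh for validation month 45:

```r
library(rollrisk)
library(data.table)

cohort <- generate_cohort(synthetic_config())
spec   <- cohort_spec()
ev     <- prepare_events(cohort$events)
flt    <- apply_cohort_filters(ev, cohort$demographics, spec)
rows   <- build_patient_months(flt$events, flt$eligible)
labeled <- code_outcome(rows[month_index < 45], ev[month_index < 45], spec,
                        horizon_end = 44, cohort$demographics)
spl     <- make_split_plan(labeled, 45, spec, split_seed = 2024)
analytic <- rbind(spl$training, spl$test)
eva      <- ev[month_index <= spl$plan$analytic_end]

dec  <- select_predictors(eva, analytic, analytic_end = spl$plan$analytic_end,
                          endpoint_codes = spec$endpoint_codes)
rec  <- recovery_report(dec, cohort$truth)
rec$planted[, .(code, multiplier, direction, prc1_p, prc2_prob, retained)]
#>          code multiplier  direction       prc1_p prc2_prob retained
#> 1:  PROT_DX_A      0.001 protective 8.214876e-04        NA     TRUE
#> 2: PROT_MED_A      0.001 protective 9.757634e-05        NA     TRUE
#> 3:  RISK_DX_A      4.000       risk 7.341753e-05 0.9860747     TRUE
#> 4:  RISK_DX_B      6.000       risk 7.341328e-15 0.9981685     TRUE
#> 5:  RISK_DX_C      8.000       risk 3.360866e-26 0.9995823     TRUE
#> 6: RISK_LAB_A      7.000       risk 2.074883e-16 0.9985037     TRUE
#> 7: RISK_MED_A      5.000       risk 4.491370e-12 0.9968745     TRUE
```

All seven planted factors are retained with the correct direction; the
false-retention rate over the 2,000 null codes is 0.001. Continuing to
the trained model and its held-out (patient-level 10% test split)
discrimination:

```r
plan  <- fit_encoding_plan(analytic, eva, cohort$demographics, dec)
dm_tr <- assemble_design_matrix(spl$training, eva, cohort$demographics, plan)
dm_te <- assemble_design_matrix(spl$test, eva, cohort$demographics, plan)
model <- train_network(build_network(ncol(dm_tr$x), model_config(train_seed = 2024)),
                       dm_tr$x, dm_tr$outcome, dm_te$x, dm_te$outcome)
p     <- predict_risk(model, dm_te$x)
bayes <- true_row_probabilities(cohort$truth,
           data.frame(patient_id = dm_te$patient_id, month_index = dm_te$month_index))
sprintf("held-out AUROC %.3f vs Bayes-optimal %.3f",
        auroc(p, dm_te$outcome), auroc(bayes, dm_te$outcome))
#> "held-out AUROC 0.907 vs Bayes-optimal 0.924"
```

The network recovers almost all of the discriminative information the
generator's true hazards contain: 0.907 against a Bayes ceiling of 0.924
(the residual gap is mostly the Bayes score's knowledge of factor onsets
that occur *inside* the future follow-up window). `run_month()` wraps all
of the above — plus validation-cohort scoring, follow-up observation and
the metric bundle — in one call, and `run_rolling()` repeats it across
months with OLS trend slopes. A CSV-in/JSON-out command-line interface
lives in `inst/scripts/roll.R`.

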