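# sctsim — synthetic control arms and trial simulation for spinal cord injury

Traumatic spinal cord injury (SCI) is a rare, heterogeneous condition, and
randomized trials struggle to recruit control arms of a useful size. A
*synthetic control* replaces the concurrent control patient with a
model-predicted counterfactual: the patient's expected recovery under
standard care, predicted from their acute ISNCSCI examination. `sctsim` is
an R package for researchers and trial methodologists who want to study
when that substitution is safe. It provides:

* the **ISNCSCI coordinate system** — 28 spinal levels, 20 key-muscle motor
  scores (0–5), UEMS/LEMS sums, cohort inclusion filters, and the
  below-NLI error metric
  `RMSE_bl.NLI = sqrt(mean over key myotomes strictly caudal to the NLI of
  (pred − obs)²)`;
* a **synthetic cohort generator** emulating the structure of a large
  European SCI registry (AIS/level/age/sex mix, assessment-time
  distributions, severity-dependent sigmoidal segmental recovery
  `s(t) = clip(s₀ + g_AIS · e^(−d/λ_AIS) · (σ(t) − σ(0))/(1 − σ(0)))`);
* a **six-family prediction benchmark** mapping an acute assessment to the
  full recovery-phase motor score sequence: ridge regression, random
  forest, gradient-boosted trees, a 1-D convolutional network along the
  myotome sequence, an attention encoder–decoder, and a graph network on
  the myotome chain (the deep models are implemented from first
  principles with verified analytic gradients);
* a **trial simulation framework**: repeated replicates draw a control
  cohort with replacement, match a zero-treatment cohort under the
  tolerances age ± 5 years, NLI ± 2 segments, sex and AIS exact, and score
  `ΔLEMS_impr` (zero-treatment minus control mean LEMS improvement) for
  randomized versus synthetic controls;
* **single-arm vs two-arm design sizes** from exact noncentral-t power:
  paired test against the counterfactual for single-arm designs,
  two-sample test for RCTs, with bootstrap uncertainty.

## Worked example

```r
library(sctsim)

# 1. generate an EMSCI-like cohort and build training instances
cohort <- generate_cohort(default_emsci_config(n_patients = 800, seed = 1))
inst   <- benchmark_inclusion(cohort)       # early <= 98 DAI, late >= 150 DAI

# 2. cross-validated benchmark: sequence model vs ridge vs no-recovery null
bench <- benchmark_models(inst,
                          list(model_spec("conv_sequence", list(epochs = 30), seed = 1),
                               model_spec("linear_regularized", seed = 1),
                               model_spec("baseline", seed = 1)),
                          k = 5, seed = 1)
subset(bench$summary, stratum == "all", c(model, rmse_median, rmse_p2.5, rmse_p97.5))
#>                 model rmse_median rmse_p2.5 rmse_p97.5
#>              baseline   0.8366600 0.0000000   1.803121
#>         conv_sequence   0.5765151 0.2859611   1.113917
#>    linear_regularized   0.5874227 0.2588796   1.107047

# 3. trial simulation: synthetic controls from a model trained on held-out patients
half  <- sort(unique(inst$patient_id))[seq_len(400)]
model <- fit_recovery_model(model_spec("conv_sequence", list(epochs = 30), seed = 1),
                            inst[inst$patient_id %in% half, ])
pool  <- trial_pool(cohort)
pool  <- pool[!pool$patient_id %in% half, ]
sim   <- repeat_trials(pool, n = 100, model, n_trials = 100, base_seed = 1)
sim$summary
#>  control_type       mean     median        q25        q75        p95
#>    randomized  0.1214000  0.1050000 -0.1225000  0.3500000  0.6825000
#>     synthetic -0.7020363 -0.7247696 -0.8917357 -0.4757184 -0.2330966

# 4. what the paired design buys: single-arm vs RCT sample size
p <- design_params(delta = 5, sd = 10, alpha = 0.05, power = 0.8)
c(single_arm = paired_n(p), rct_per_group = two_sample_n(p))
#>    single_arm rct_per_group
#>            34            64
```

Reading the output: the sequence model cuts the median below-NLI error of
the no-recovery null from 0.84 to 0.58 motor points and edges out ridge. In
the simulation, randomized controls scatter around zero (median 0.11); the
synthetic-control delta is centred at the model's cohort-level bias
(−0.72 points here — a diagnostic the framework is designed to expose, and
exactly zero for a perfect counterfactual). With outcome SD 10 and a
5-point detectable effect, a synthetic-control single-arm trial needs 34
patients where an RCT needs 64 per group (128 total) — if, and only if,
the paired SD is genuinely below the two-sample SD.

A command-line wrapper with subcommands `generate`, `include`, `train`,
`simulate`, `power`, and `run` (full pipeline) is in
`inst/cli/sctsim.R`.

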