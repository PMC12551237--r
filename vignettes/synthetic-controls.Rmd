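---
title: "Synthetic control arms for spinal cord injury trials: models, simulation design, and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic control arms for spinal cord injury trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctsim)
```

## The problem

Traumatic spinal cord injury (SCI) is rare and clinically heterogeneous, so
randomized trials struggle to recruit control arms of a useful size. A
*synthetic control* replaces the concurrent control patient with a
model-based prediction of that patient's recovery under standard care: the
counterfactual outcome. If the prediction is good enough, a trial can
enrol every patient in the treatment arm and test the outcome against the
predicted counterfactuals with a paired test.

`sctsim` implements this idea end to end for the ISNCSCI examination, the
standard neurological assessment in SCI: predict the full recovery-phase
sequence of the 20 key-muscle motor scores (0–5 each) from an acute
assessment, use the predictions as synthetic controls, quantify how they
behave against randomized controls in repeated simulated trials, and
translate the result into single-arm versus two-arm sample sizes.

## Coordinate system and derived scores

All quantities live on the 28-level rostro-caudal spinal axis (C2 … S4-5).
The 10 key muscles (C5–T1, L2–S1) carry a motor score per side; UEMS and
LEMS are the cervical and lumbosacral sums (0–50 each). Prediction error is
always reported *below the initial neurological level of injury* (NLI):
the root mean squared error over the key-muscle coordinates strictly caudal
to the NLI, both sides (`rmse_bl_nli()`). This makes errors comparable
across lesion levels. Where the choice was open we count both sides of
every strictly caudal key muscle (16 coordinates for a C6 lesion, 10 for a
mid-thoracic one), and we treat AIS grade and NLI as given inputs — the
package never re-derives them from the raw scores.

Records with missing or out-of-range scores are rejected at the I/O
boundary with the offending row; no imputation is attempted. Cohort filters
follow the conventions of large SCI registries: an early assessment within
98 days after injury (DAI) plus a late one at 150+ DAI, AIS grades A–D,
NLI rostral to S1, and exclusion of patients showing a motor-score
deterioration of two or more points (observational registries do not record
the complications that cause deterioration, so it cannot be modelled). The
case-study filter keeps cervical lesions (C2–C8 inclusive — high cervical
lesions are cervical), baseline within 28 DAI, follow-up in the closed
window [161, 175] DAI, and baseline UEMS below 29.

## The synthetic cohort generator

Real SCI registry data are restricted, so the package ships a generator
(`generate_cohort()`) that emulates the published structure of a large
European registry cohort. The default configuration
(`default_emsci_config()`) fixes:

* AIS mix 43.1 / 12.5 / 18.1 / 26.0 % (A–D, renormalized), injury-region
  mix 53.8 / 37.3 / 9.0 % (cervical / thoracic / lumbar), NLI uniform
  within a region;
* age 46 (SD 18) years floored at 16; 22.1 % female;
* first assessment at 22 (SD 20) DAI truncated to [0, 98]; follow-up at
  216 (SD 91) DAI truncated at 150;
* voluntary anal contraction present in 30.5 % and deep anal pressure in
  52.4 % overall, generated from AIS-conditional probabilities
  (VAC: 0.03/0.15/0.40/0.77, DAP: 0.245/0.55/0.70/0.85 for A–D) chosen so
  the marginals match; the conditional split itself is a modelling choice.

Recovery is modelled as a logistic time course anchored at the baseline:

\[
s(t) = \mathrm{clip}\Big(s_0 + g_{\mathrm{AIS}}\,
  e^{-d/\lambda_{\mathrm{AIS}}}\,
  \frac{\sigma(t) - \sigma(0)}{1 - \sigma(0)}, \; 0, 5\Big),
\qquad \sigma(t) = \mathrm{logistic}\!\big((t - t_{1/2})/\tau\big),
\]

with plateau gain \(g\) (points; A 1.0, B 2.0, C 3.0, D 2.5), midpoint
\(t_{1/2} = 60\) DAI, time constant \(\tau = 30\) days, and an attenuation
length \(\lambda\) in segments caudal to the NLI. The attenuation length is
severity-dependent (A 3, B 6, C 12, D 20 segments): complete injuries
recover only near the lesion, incomplete ones also distally. A single short
attenuation for every grade would abolish lumbosacral recovery after
cervical injury for all severities, contradicting both clinical experience
and the qualitative ordering the package asserts in its tests (mean LEMS
improvement AIS D > AIS A). Baseline scores are 5 rostral to the NLI and
decay caudally to an AIS-dependent plateau (0 / 0.5 / 2.0 / 3.5 points);
for AIS A the baseline is exactly 0 below the lesion (complete-injury
convention), and noise is only applied where residual function exists.

Noise is Gaussian per coordinate (SD 0.6 points) with a latent component
shared between the left and right score of a level (correlation 0.8), then
rounded and clipped — this left/right and rostro-caudal structure is what
sequence-aware models can exploit. Late integer scores are floored at
(early − 1), so the generator never produces the ≥ 2-point deterioration
that the inclusion filter would remove.

The generator reproduces marginal compositions, spatial score correlation,
and severity-dependent sigmoidal recovery. It does **not** emulate real
inter-rater assessment error structure, secondary complications, missing
data patterns, multi-visit trajectories (each patient has exactly two
assessments), or covariate effects of age and sex on recovery. Tests that
pass on generated cohorts therefore validate the *machinery* — metrics,
matching, simulation logic, power arithmetic — and the *relative* behaviour
of model families under spatially structured signal; they are not evidence
about absolute predictive performance on real patients.

## Prediction model families

`fit_recovery_model()` trains one of six families on encoded instances
(60 sequence features: motor, light-touch and pinprick score per key-muscle
coordinate; 11 scalars: age, sex, both assessment times, AIS one-hot, VAC,
DAP, NLI index). Targets are the 20 late motor scores, trained as
continuous regressions and evaluated unrounded; predictions are clipped to
[0, 5].

* `linear_regularized` — ridge regression per coordinate (glmnet), penalty
  chosen per coordinate by inner 5-fold CV over a fixed grid
  \(10^{-3} \ldots 10^{3}\).
* `random_forest`, `gradient_boosted_trees` — one ranger forest (150
  trees) / xgboost booster (80 rounds, depth 4, learning rate 0.1) per
  coordinate.
* `conv_sequence` — 1-D convolutions (kernel 3, two layers, 32 filters)
  along the 10 key-muscle positions, with 6 modality channels plus
  broadcast scalars, and a per-position linear head for the left/right
  scores.
* `seq2seq_attention` — position-wise encoder embeddings with learned
  positional terms; 10 learned queries (one per output level) attend over
  the encoded acute sequence by scaled dot-product softmax.
* `graph_sequence` — two rounds of message passing on the 20-node myotome
  graph (chain edges between consecutive key muscles within a side,
  left–right cross edges, self loops; symmetrically normalized adjacency).

The three deep families are implemented from first principles (explicit
analytic backpropagation, minibatch Adam, ~5–25k parameters); their
gradients are verified against finite differences in the test suite, and
every family trains in seconds on a few thousand instances with one CPU.
Determinism: all training randomness derives from the spec seed, and the
training table is sorted canonically first, so fitting is invariant to row
order. Cross-validation folds are split by patient — instances of one
patient never straddle train and test.

Reference predictors close the loop for validation: `baseline`
(carry-forward of the acute scores, the no-recovery null), `oracle`
(returns the observed late scores — the perfect counterfactual), and
`noisy_oracle` (oracle plus Gaussian noise that is a deterministic function
of seed and patient, so the same patient always receives the same
counterfactual perturbation).

Input uncertainty is propagated by perturbation (`perturb_predict()`): each
score is jittered by ±1 with probability 0.1 (a pragmatic stand-in for
assessment test–retest uncertainty, which is not publicly quantified per
myotome), and the 2.5th/97.5th percentiles over replicates form the band.
With few replicates an interpolated percentile can land inside the
unperturbed prediction, so the band is clamped to contain the point.
Feature importance uses permutation importance (increase in MSE when a
feature column is permuted), with the backend recorded in the result;
importances aggregate by signed segment distance to the endpoint myotome,
laterality, and modality.

## Trial simulation design

Each replicate draws a control cohort of size *n* with replacement from the
eligible pool (baseline ≤ 40 DAI, one instance per patient: earliest and
latest assessment), optionally stratified to a requested AIS composition
(largest-remainder rounding) and plegia (tetraplegia = cervical NLI,
paraplegia = thoracic/lumbar). A zero-treatment cohort is then matched
pairwise under the published tolerances: age ± 5 years, NLI ± 2 segments,
sex and AIS grade exact. The endpoint is the difference in mean LEMS
improvement, with the zero-treatment arm first:
\(\Delta_{\mathrm{rand}} = \overline{\mathrm{impr}}_{\mathrm{ZT,obs}} -
\overline{\mathrm{impr}}_{\mathrm{ctrl,obs}}\) and
\(\Delta_{\mathrm{synth}} = \overline{\mathrm{impr}}_{\mathrm{ZT,obs}} -
\overline{\mathrm{impr}}_{\mathrm{ZT,pred}}\). Percentile summaries are
computed on the signed differences by default, with an absolute-value
variant behind a flag.

Three matching design choices deserve explanation:

* **Candidate ranking.** Greedy sequential matching in random member
  order; candidates within tolerance are ranked by NLI gap first and age
  gap second, random tie-break, without replacement (reuse only when the
  pool is exhausted, with a warning). Age proximity alone lets the matched
  NLI drift near region-density boundaries: the ±2-segment window then
  contains more candidates on the denser side, and the matched cohort's
  level distribution — which drives recovery — shifts systematically.
  Ranking the discrete, outcome-relevant level first removes that drift
  while age remains within ± 5 years by the eligibility constraint.
* **Self-exclusion only.** Each member's own patient is excluded from its
  candidates, which is what prevents a trivial self-match. Excluding the
  *entire* drawn control cohort instead makes rare covariate profiles
  (e.g. female, AIS B, lumbar lesion, extreme age) unmatchable — such a
  profile often has exactly one compatible partner in a realistic pool —
  and most replicates then fail. The stricter variant remains available
  (`exclude = "drawn"`), as does `exclude = "none"` for identity checks.
* **Common support.** `repeat_trials()` first drops pool patients with no
  tolerance-compatible partner at all (typically ~1 % of a 3000-patient
  pool), the standard overlap condition of matching designs. Every drawn
  control is then matchable by construction and replicates cannot fail at
  the matching stage; `run_replicate()` on an unrestricted pool still
  raises a matching-failure error naming the member.

One subtlety matters when interpreting repeated simulations: conditional on
a single finite pool, the mean of \(\Delta_{\mathrm{rand}}\) over
replicates is *not* exactly zero. Deterministic nearest-candidate matching
weights patients unevenly within covariate cells, and those weights
correlate by chance with the pool's realized recovery noise — an offset of
order 0.05 LEMS points for a 3000-patient pool that no number of replicates
removes. Unbiasedness holds over the population of cohorts, so the
package's zero-effect test averages 500 replicates over 50 independently
generated cohorts; with an oracle counterfactual the synthetic delta is
exactly zero in every replicate regardless.

## Sample-size machinery

Synthetic controls change the test, not just the control arm: the outcome
is evaluated with a paired t-test against the predicted counterfactual, so
the relevant variability is the standard deviation of the *paired
differences* (observed minus predicted improvement), while a two-arm design
faces the full per-observation SD. `paired_n()` and `two_sample_n()` return
the smallest n reaching the target power for the two-sided test, by
iteration over n with exact noncentral-t power — a normal approximation is
off by a couple of patients at these sizes, which matters for the
comparison. Two-sided \(\alpha\) throughout (sidedness is not stated in the
sources this mirrors; two-sided is the conservative standard).
`estimate_design_inputs()` derives both SDs from data plus a model, flags a
constant prediction shift as bias (a shift leaves the paired SD untouched),
and `bootstrap_design()` quantifies the sampling uncertainty of both design
sizes by patient-level resampling (default 1000 resamples; zero-variance
resamples are counted and skipped). Degenerate paired comparisons (zero
variance of the differences) report an undefined t statistic rather than
failing.

## Numerical conventions

Percentiles use linear interpolation between order statistics (R type 7).
The error-versus-time profile takes the daily median over the day of the
initial assessment and smooths with a centered 7-day rolling mean over the
days that have data (minimum one). Sequence outputs are ordered
rostro-caudally with left before right within a level, everywhere. Seeds
fan out from a single integer per entry point; regeneration, refitting and
resimulation with the same seed are bit-identical.

## Problem sizes used for validation

The shipped validation uses sizes chosen to exercise every code path at
desk scale: 2000-patient cohorts with 5-fold patient-level CV for the
benchmark ordering (sequence model ≤ ridge, both well below the
carry-forward null); 500-trial simulations at cohort sizes 100–400; 100k
Monte-Carlo replicates for verifying the power computations; and a
600-patient cervical cohort for the case-study path. The pipeline demo
(`run_pipeline()`) defaults to 500 patients and 50 trials.

## Known limitations

* Generator realism bounds what synthetic experiments can show (see
  above); absolute error levels on real registry data will differ.
* The perturbation magnitude for input uncertainty is a package default,
  not an estimate from inter-rater studies.
* Matching assumes the pool is large relative to the trial; with small
  pools candidate reuse (logged) weakens the independence of matched
  pairs.
* The importance backend is permutation-based; Shapley-value attributions
  would distribute credit differently for correlated features, which
  segmental scores are by construction.
* Sample-size results assume approximately normal outcome differences and
  equal variances in the two-arm case.
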