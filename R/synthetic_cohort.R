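# Synthetic EMSCI-like cohort generator.
#
# Real registry data on spinal cord injury recovery are restricted, so the
# package ships a generator that emulates the published cohort structure:
# the AIS-grade and injury-level mix, age/sex distribution, assessment-time
# distributions, and a severity-dependent sigmoidal segmental recovery with
# exponential attenuation of both baseline sparing and recovery with distance
# caudal to the NLI. Left/right scores share a per-level latent so that
# neighbouring and contralateral scores carry exploitable correlation.

REGION_LEVELS <- list(
  cervical = SPINAL_LEVELS[1:7],       # C2-C8
  thoracic = SPINAL_LEVELS[8:19],      # T1-T12
  lumbar   = SPINAL_LEVELS[20:24]      # L1-L5
)

#' Cohort generator configuration
#'
#' All knobs of the synthetic cohort generator. Defaults come from
#' [default_emsci_config()]; every parameter can be overridden.
#'
#' @param n_patients Number of patients to generate.
#' @param ais_mix Named probabilities over AIS grades A-D (normalized).
#' @param nli_region_mix Named probabilities over cervical/thoracic/lumbar.
#' @param age_mean,age_sd Age at injury, years (truncated at `age_min`).
#' @param age_min Minimum age (adult registry; default 16).
#' @param frac_female Proportion of female patients.
#' @param t_early_mean,t_early_sd Days after injury of the first assessment
#'   (normal, truncated to `[0, t_early_max]`).
#' @param t_early_max Ceiling for the first assessment time (default 98).
#' @param t_late_mean,t_late_sd Days after injury of the follow-up
#'   (normal, truncated at `t_late_min`).
#' @param t_late_min Floor for the follow-up time (default 150).
#' @param gain Named per-AIS plateau recovery gain in motor points at the
#'   segment just caudal to the NLI.
#' @param rate Logistic time constant of recovery, days.
#' @param midpoint Logistic midpoint of recovery, days after injury.
#' @param decay_per_segment Named per-AIS attenuation length (segments) of
#'   recovery caudal to the NLI: complete injuries recover only near the
#'   lesion, incomplete injuries also distally.
#' @param baseline_plateau Named per-AIS caudal baseline motor plateau
#'   (points, 0-5): 0 for complete injuries, higher for incomplete.
#' @param baseline_decay Named per-AIS attenuation length (segments) of the
#'   above-plateau baseline sparing just caudal to the NLI; near zero for
#'   AIS A, whose baseline is exactly 0 caudal to the lesion (noise is only
#'   applied where residual function exists).
#' @param noise_sd Ordinal noise scale (points) added before rounding.
#' @param lr_correlation Left/right (and within-level) score correlation via
#'   a shared latent; 0-1.
#' @param vac_prob,dap_prob Named per-AIS probabilities of present VAC/DAP.
#' @param seed Integer seed recorded in the cohort provenance.
#' @return A list of class `sci_cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000L,
                          ais_mix = c(A = 0.431, B = 0.125, C = 0.181, D = 0.260),
                          nli_region_mix = c(cervical = 0.538, thoracic = 0.373,
                                             lumbar = 0.090),
                          age_mean = 46, age_sd = 18, age_min = 16,
                          frac_female = 0.221,
                          t_early_mean = 22, t_early_sd = 20, t_early_max = 98,
                          t_late_mean = 216, t_late_sd = 91, t_late_min = 150,
                          gain = c(A = 1.0, B = 2.0, C = 3.0, D = 2.5),
                          rate = 30, midpoint = 60,
                          decay_per_segment = c(A = 3, B = 6, C = 12, D = 20),
                          baseline_plateau = c(A = 0, B = 0.5, C = 2.0, D = 3.5),
                          baseline_decay = c(A = 1e-6, B = 1.0, C = 1.5, D = 2.0),
                          noise_sd = 0.6,
                          lr_correlation = 0.8,
                          vac_prob = c(A = 0.03, B = 0.15, C = 0.40, D = 0.77),
                          dap_prob = c(A = 0.245, B = 0.55, C = 0.70, D = 0.85),
                          seed = 1L) {
  ais_mix <- ais_mix / sum(ais_mix)
  nli_region_mix <- nli_region_mix / sum(nli_region_mix)
  stopifnot(n_patients >= 1, age_sd > 0, t_early_sd > 0, t_late_sd > 0,
            noise_sd >= 0, lr_correlation >= 0, lr_correlation <= 1,
            abs(sum(ais_mix) - 1) < 1e-9, abs(sum(nli_region_mix) - 1) < 1e-9)
  structure(as.list(environment()), class = "sci_cohort_config")
}

#' Default EMSCI-like configuration
#'
#' Generator configuration reproducing the published marginal structure of a
#' large European SCI registry cohort: AIS mix 43.1/12.5/18.1/26.0% (A-D,
#' renormalized), injury-level region mix 53.8/37.3/9.0%
#' (cervical/thoracic/lumbar), age 46 (SD 18) years, 22.1% female, first
#' assessment at 22 (SD 20) DAI and follow-up at 216 (SD 91) DAI (truncated
#' at 150), VAC present in 30.5% and DAP in 52.4% (via AIS-conditional
#' probabilities chosen to reproduce these marginals).
#'
#' @param n_patients Number of patients (default 1000).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @return An `sci_cohort_config`.
#' @export
default_emsci_config <- function(n_patients = 1000L, seed = 1L, ...) {
  cohort_config(n_patients = n_patients, seed = seed, ...)
}

#' Expected segmental recovery trajectory
#'
#' The noise-free recovery model of the generator: a logistic time course,
#' anchored so the score equals the baseline exactly at `t = 0`, scaled by an
#' AIS-dependent plateau gain and attenuated exponentially with segment
#' distance caudal to the NLI, then clipped to the motor-score range.
#'
#' `score(t) = clip(baseline + gain(ais) * exp(-distance / lambda) *
#'   (s(t) - s(0)) / (1 - s(0)))` with `s(t) = plogis((t - midpoint) / rate)`.
#' The trajectory is monotone non-decreasing in `t`.
#'
#' @param baseline_score Baseline motor score (0-5), vectorized.
#' @param ais AIS grade(s) indexing the plateau gain.
#' @param distance Segments caudal to the NLI (>= 0).
#' @param t Days after injury (>= 0).
#' @param p An `sci_cohort_config` carrying `gain`, `rate`, `midpoint`,
#'   `decay_per_segment`.
#' @return Expected score(s) in \[0, 5\].
#' @export
expected_trajectory <- function(baseline_score, ais, distance, t, p) {
  stopifnot(all(t >= 0))
  s0 <- stats::plogis(-p$midpoint / p$rate)
  st <- stats::plogis((t - p$midpoint) / p$rate)
  inc <- unname(p$gain[ais]) *
    exp(-pmax(distance, 0) / unname(p$decay_per_segment[ais])) *
    (st - s0) / (1 - s0)
  pmin(pmax(baseline_score + inc, 0), 5)
}

# Continuous baseline motor profile: 5 rostral to / at the NLI, decaying to
# an AIS-dependent plateau caudally.
baseline_profile <- function(distance, ais, p) {
  plateau <- p$baseline_plateau[ais]
  ifelse(distance <= 0, 5,
         plateau + (5 - plateau) * exp(-distance / p$baseline_decay[ais]))
}

# Correlated per-coordinate noise: a latent shared within a level (both
# sides) plus an independent component, total sd = noise_sd.
level_noise <- function(levels_n, sd, rho) {
  shared <- stats::rnorm(levels_n, 0, sd * sqrt(rho))
  list(left = shared + stats::rnorm(levels_n, 0, sd * sqrt(1 - rho)),
       right = shared + stats::rnorm(levels_n, 0, sd * sqrt(1 - rho)))
}

round_clip <- function(x, hi) pmin(pmax(round(x), 0), hi)

#' Sample one synthetic patient
#'
#' Draws demographics, injury characteristics and a two-assessment recovery
#' trajectory from the generator model. Uses the current R random number
#' stream; seed via `set.seed()` or use [generate_cohort()].
#'
#' Baseline motor scores are 5 rostral to the NLI and attenuate caudally to
#' an AIS-dependent plateau (0 for AIS A, the complete-injury convention);
#' the late assessment follows [expected_trajectory()] plus correlated,
#' discretized noise. Late integer scores are floored at `early - 1` so the
#' generator never produces a >= 2-point deterioration (complication-driven
#' deterioration is excluded from the modelled population).
#'
#' @param config An `sci_cohort_config`.
#' @param patient_id Identifier for the record.
#' @return An `sci_patient` with two assessments.
#' @export
sample_patient <- function(config, patient_id = "P1") {
  p <- config
  age <- max(p$age_min, stats::rnorm(1, p$age_mean, p$age_sd))
  sex <- if (stats::runif(1) < p$frac_female) "female" else "male"
  ais <- sample(names(p$ais_mix), 1, prob = p$ais_mix)
  region <- sample(names(p$nli_region_mix), 1, prob = p$nli_region_mix)
  nli <- sample(REGION_LEVELS[[region]], 1)
  t_early <- as.integer(round(min(p$t_early_max,
                                  max(0, stats::rnorm(1, p$t_early_mean, p$t_early_sd)))))
  t_late <- as.integer(round(max(p$t_late_min,
                                 stats::rnorm(1, p$t_late_mean, p$t_late_sd))))
  if (t_late <= t_early) t_late <- t_early + 1L

  nli_i <- level_index(nli)
  key_d <- level_index(KEY_MUSCLES) - nli_i     # segments caudal to NLI
  all_d <- level_index(SPINAL_LEVELS) - nli_i

  # baseline motor, correlated across sides within a level
  mu_m <- baseline_profile(key_d, ais, p)
  eps <- level_noise(length(KEY_MUSCLES), p$noise_sd, p$lr_correlation)
  # denervated segments (expected score ~0, e.g. all of AIS A caudally) stay
  # exactly 0 at baseline: complete injuries show no residual motor function
  noisy_baseline <- function(e) {
    ifelse(key_d <= 0, 5,
           ifelse(mu_m < 0.05, 0, round_clip(mu_m + e, 5)))
  }
  motor_e <- list(left = noisy_baseline(eps$left), right = noisy_baseline(eps$right))

  # sensory on the 0-2 scale, same spatial structure
  mu_s <- baseline_profile(all_d, ais, p) * 2 / 5
  sense <- function() {
    e <- level_noise(length(SPINAL_LEVELS), p$noise_sd * 2 / 5, p$lr_correlation)
    nb <- function(eps1) {
      ifelse(all_d <= 0, 2,
             ifelse(mu_s < 0.02, 0, round_clip(mu_s + eps1, 2)))
    }
    list(left = nb(e$left), right = nb(e$right))
  }
  lt_e <- sense(); pp_e <- sense()

  vac <- stats::runif(1) < p$vac_prob[ais]
  dap <- stats::runif(1) < p$dap_prob[ais]

  named_by_side <- function(x, levels) {
    stats::setNames(as.vector(rbind(x$left, x$right)),
                    as.vector(t(outer(levels, SIDES, paste, sep = "_"))))
  }
  early <- new_assessment(patient_id, t_early,
                          motor = named_by_side(motor_e, KEY_MUSCLES),
                          light_touch = named_by_side(lt_e, SPINAL_LEVELS),
                          pinprick = named_by_side(pp_e, SPINAL_LEVELS),
                          vac = vac, dap = dap, ais = ais, nli = nli)

  # late assessment: expected trajectory from the *continuous* baseline plus
  # fresh correlated noise; never more than 1 point below the early score
  traj <- function(side_scores) {
    expected_trajectory(side_scores, ais, pmax(key_d, 0), t_late, p)
  }
  eps2 <- level_noise(length(KEY_MUSCLES), p$noise_sd, p$lr_correlation)
  motor_l <- list(
    left = pmax(round_clip(traj(motor_e$left) + eps2$left, 5), motor_e$left - 1),
    right = pmax(round_clip(traj(motor_e$right) + eps2$right, 5), motor_e$right - 1))

  sens_traj <- function(x) {
    g2 <- p$gain[ais] * 2 / 5
    s0 <- stats::plogis(-p$midpoint / p$rate)
    st <- stats::plogis((t_late - p$midpoint) / p$rate)
    inc <- g2 * exp(-pmax(all_d, 0) / p$decay_per_segment[ais]) * (st - s0) / (1 - s0)
    e <- level_noise(length(SPINAL_LEVELS), p$noise_sd * 2 / 5, p$lr_correlation)
    list(left = pmax(round_clip(x$left + inc + e$left, 2), x$left - 1),
         right = pmax(round_clip(x$right + inc + e$right, 2), x$right - 1))
  }
  lt_l <- sens_traj(lt_e); pp_l <- sens_traj(pp_e)

  late <- new_assessment(patient_id, t_late,
                         motor = named_by_side(motor_l, KEY_MUSCLES),
                         light_touch = named_by_side(lt_l, SPINAL_LEVELS),
                         pinprick = named_by_side(pp_l, SPINAL_LEVELS),
                         vac = vac || (ais %in% c("C", "D") && stats::runif(1) < 0.2),
                         dap = dap, ais = ais, nli = nli)

  new_patient_record(patient_id, age, sex, list(early, late))
}

#' Generate a synthetic cohort
#'
#' Draws `config$n_patients` independent patients. Regeneration with the same
#' config (including seed) is bit-identical.
#'
#' @param config An `sci_cohort_config`.
#' @return An `sci_cohort`: list with `records`, `config`, `provenance`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sci_cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  records <- lapply(seq_len(config$n_patients), function(i) {
    sample_patient(config, patient_id = sprintf("SYN%05d", i))
  })
  structure(list(records = records, config = config,
                 provenance = list(seed = config$seed, generator = "sctsim-1")),
            class = "sci_cohort")
}

#' @export
print.sci_cohort <- function(x, ...) {
  cat(sprintf("<synthetic SCI cohort: %d patients, seed %d>\n",
              length(x$records), x$provenance$seed))
  invisible(x)
}
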