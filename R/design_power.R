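# Single-arm versus two-arm sample-size machinery.
#
# Synthetic controls turn a between-group comparison into a within-patient
# one: the outcome is tested with a paired t-test against the predicted
# counterfactual, so the relevant variability is the SD of the paired
# differences rather than the per-observation SD. Sample sizes use exact
# noncentral-t power (a normal approximation is off by a couple of patients
# at these sizes), two-sided throughout.

#' Design parameters for sample-size calculation
#'
#' @param delta Detectable treatment effect in motor points (> 0).
#' @param sd Outcome standard deviation: per-observation SD for two-sample
#'   designs, SD of the paired differences for single-arm designs.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return List of class `sci_design_params`.
#' @export
design_params <- function(delta, sd, alpha = 0.05, power = 0.8) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  structure(list(delta = delta, sd = sd, alpha = alpha, power = power),
            class = "sci_design_params")
}

power_one_sample <- function(n, delta, sd, alpha) {
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- delta / (sd / sqrt(n))
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

power_two_sample <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- delta / (sd * sqrt(2 / n))
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

smallest_n <- function(powfun, p, n_max = 1e6) {
  n <- 2
  while (n <= n_max) {
    if (powfun(n, p$delta, p$sd, p$alpha) >= p$power) return(as.integer(n))
    n <- n + 1
  }
  stop("target power unreachable with these parameters")
}

#' Sample size of a single-arm (paired) design
#'
#' Smallest number of patients for which a two-sided one-sample t-test on
#' the paired differences (observed outcome minus synthetic-control
#' outcome) reaches the target power, by iteration over n with exact
#' noncentral-t power.
#'
#' @param p An `sci_design_params` with `sd` = SD of paired differences.
#' @return Integer number of patients.
#' @export
#' @examples
#' paired_n(design_params(delta = 5, sd = 10)) # 34
paired_n <- function(p) {
  stopifnot(inherits(p, "sci_design_params"))
  smallest_n(power_one_sample, p)
}

#' Per-group sample size of a two-arm design
#'
#' Smallest per-group n for which a two-sided two-sample t-test (equal
#' arms, equal variance) reaches the target power, exact noncentral-t with
#' 2n - 2 degrees of freedom.
#'
#' @param p An `sci_design_params` with `sd` = per-observation SD.
#' @return Integer patients per group (total is twice this).
#' @export
#' @examples
#' two_sample_n(design_params(delta = 5, sd = 10)) # 64 per group
two_sample_n <- function(p) {
  stopifnot(inherits(p, "sci_design_params"))
  smallest_n(power_two_sample, p)
}

#' Estimate design variability inputs from data
#'
#' From instances meeting the case-study inclusion criteria and a fitted
#' model: the per-observation SD of the observed UEMS improvement (two-arm
#' design input) and the SD of the per-patient difference between observed
#' and synthetic-control UEMS improvement (single-arm design input). A
#' constant prediction shift leaves `sd_paired` untouched but is flagged as
#' `bias`.
#'
#' @param instances An `sci_instances` table (>= 3 rows).
#' @param model An `sci_recovery_model` trained on other patients.
#' @return List `sd_two_sample`, `sd_paired`, `bias` (mean observed minus
#'   synthetic improvement), `n`.
#' @export
estimate_design_inputs <- function(instances, model) {
  if (nrow(instances) < 3) stop("need at least 3 instances")
  obs <- uems_improvement(instances)
  synth <- uems_improvement(instances, late = predict(model, instances))
  diffs <- obs - synth
  list(sd_two_sample = stats::sd(obs), sd_paired = stats::sd(diffs),
       bias = mean(diffs), n = nrow(instances))
}

#' Bootstrap distribution of design sizes
#'
#' Resamples instances with replacement, re-estimates both SDs and the
#' resulting single-arm size and two-arm total per resample, and reports
#' median and 2.5th/97.5th percentiles.
#'
#' @param instances An `sci_instances` table.
#' @param model An `sci_recovery_model`.
#' @param delta,alpha,power Design parameters (defaults 5 motor points,
#'   0.05, 0.8).
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Integer seed.
#' @return List with `single_arm` and `rct_total` (each: `point`, `median`,
#'   `p2.5`, `p97.5`), `degenerate` (count of zero-variance resamples,
#'   skipped), and the point `inputs`.
#' @export
bootstrap_design <- function(instances, model, delta = 5, alpha = 0.05,
                             power = 0.8, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 100)
  inputs <- estimate_design_inputs(instances, model)
  point_single <- paired_n(design_params(delta, inputs$sd_paired, alpha, power))
  point_rct <- 2L * two_sample_n(design_params(delta, inputs$sd_two_sample,
                                               alpha, power))
  sizes <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(instances), replace = TRUE)
      bi <- tryCatch(estimate_design_inputs(instances[idx, , drop = FALSE], model),
                     error = function(e) NULL)
      if (is.null(bi) || bi$sd_paired <= 0 || bi$sd_two_sample <= 0) {
        return(c(NA_real_, NA_real_))
      }
      c(paired_n(design_params(delta, bi$sd_paired, alpha, power)),
        2 * two_sample_n(design_params(delta, bi$sd_two_sample, alpha, power)))
    }, numeric(2))
  })
  degenerate <- sum(is.na(sizes[1, ]))
  s1 <- sizes[1, !is.na(sizes[1, ])]
  s2 <- sizes[2, !is.na(sizes[2, ])]
  summ <- function(point, v) {
    list(point = point, median = stats::median(v),
         p2.5 = pct(v, 0.025), p97.5 = pct(v, 0.975))
  }
  list(single_arm = summ(point_single, s1), rct_total = summ(point_rct, s2),
       degenerate = degenerate, inputs = inputs)
}

#' Compare two outcome groups
#'
#' Group means with empirical 2.5th/97.5th percentiles and a two-sided
#' t-test of the stated type: paired when the groups are aligned
#' per-patient (the synthetic-control situation), two-sample otherwise.
#'
#' @param group_a,group_b Numeric outcome vectors (e.g. UEMS improvement).
#' @param paired Logical; if TRUE, lengths must match.
#' @return List of class `sci_arm_comparison`: per-group `mean`, `p2.5`,
#'   `p97.5`; `statistic`, `p_value`, `test`.
#' @export
arm_compare <- function(group_a, group_b, paired = FALSE) {
  if (paired && length(group_a) != length(group_b)) {
    stop("paired comparison requires aligned groups of equal length")
  }
  tt <- tryCatch(
    stats::t.test(group_a, group_b, paired = paired, var.equal = !paired),
    error = function(e) {
      # zero-variance differences (e.g. a perfect or constant-shift
      # counterfactual): the t statistic is undefined
      list(statistic = c(t = NA_real_), p.value = NA_real_)
    })
  structure(list(
    a = list(mean = mean(group_a), p2.5 = pct(group_a, 0.025),
             p97.5 = pct(group_a, 0.975)),
    b = list(mean = mean(group_b), p2.5 = pct(group_b, 0.025),
             p97.5 = pct(group_b, 0.975)),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    test = if (paired) "paired" else "two-sample"),
    class = "sci_arm_comparison")
}

#' @export
print.sci_arm_comparison <- function(x, ...) {
  cat(sprintf("<%s t-test: A %.2f (%.2f, %.2f) vs B %.2f (%.2f, %.2f); t = %.3f, p = %.3f>\n",
              x$test, x$a$mean, x$a$p2.5, x$a$p97.5, x$b$mean, x$b$p2.5,
              x$b$p97.5, x$statistic, x$p_value))
  invisible(x)
}
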