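# Randomized-versus-synthetic-control trial simulation.
#
# A replicate draws a control cohort with replacement from the eligible
# pool, builds a covariate-matched "zero-treatment" cohort (patients who
# would receive the investigative treatment in an RCT but, the data being
# observational, just recover naturally), and scores the endpoint
#   delta_randomized = mean LEMS_impr(zero-treatment, observed)
#                    - mean LEMS_impr(control, observed)
#   delta_synthetic  = mean LEMS_impr(zero-treatment, observed)
#                    - mean LEMS_impr(zero-treatment, predicted)
# Under no treatment both deltas should be centred at zero; their spread
# quantifies the trial-outcome uncertainty of each control mechanism.

#' Matching tolerances
#'
#' @param age_years Maximum absolute age difference (default 5).
#' @param nli_segments Maximum absolute NLI distance in segments (default 2).
#' @param sex_exact,ais_exact Require exact agreement (default TRUE).
#' @return List of class `sci_match_tol`.
#' @export
match_tolerances <- function(age_years = 5, nli_segments = 2,
                             sex_exact = TRUE, ais_exact = TRUE) {
  stopifnot(age_years >= 0, nli_segments >= 0)
  structure(list(age_years = age_years, nli_segments = nli_segments,
                 sex_exact = sex_exact, ais_exact = ais_exact),
            class = "sci_match_tol")
}

#' Common-support restriction of a matching pool
#'
#' Drops patients that have no tolerance-compatible partner (another patient
#' agreeing on sex and AIS grade within the age and NLI tolerances) anywhere
#' in the pool. Controls drawn from the restricted pool are always
#' matchable, so trial replicates cannot fail at the matching stage; the
#' number of dropped patients is recorded in the `dropped` attribute.
#'
#' @param pool An `sci_instances` pool (one row per patient).
#' @param tol An `sci_match_tol`.
#' @return The filtered pool with attribute `dropped`.
#' @export
common_support <- function(pool, tol = match_tolerances()) {
  n <- nrow(pool)
  has_partner <- logical(n)
  for (i in seq_len(n)) {
    ok <- abs(pool$age - pool$age[i]) <= tol$age_years &
      abs(pool$nli_index - pool$nli_index[i]) <= tol$nli_segments &
      pool$patient_id != pool$patient_id[i]
    if (tol$sex_exact) ok <- ok & pool$sex == pool$sex[i]
    if (tol$ais_exact) ok <- ok & pool$ais == pool$ais[i]
    has_partner[i] <- any(ok)
  }
  out <- pool[has_partner, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!has_partner)
  out
}

#' Draw a control cohort with replacement
#'
#' Uniform draws with replacement from the eligible pool; when `ais_mix` is
#' given, draws are stratified by AIS grade to hit the requested composition
#' (counts by largest remainder).
#'
#' @param pool An `sci_instances` pool (one row per patient).
#' @param n Cohort size.
#' @param ais_mix Optional named probabilities over AIS grades.
#' @param plegia `"both"`, `"tetraplegia"` (cervical NLI) or `"paraplegia"`
#'   (thoracic/lumbar NLI).
#' @return Integer vector of pool row indices (length `n`).
#' @export
draw_control <- function(pool, n, ais_mix = NULL, plegia = "both") {
  elig <- seq_len(nrow(pool))
  if (plegia == "tetraplegia") elig <- elig[pool$nli_index <= level_index("C8")]
  if (plegia == "paraplegia") elig <- elig[pool$nli_index > level_index("C8")]
  if (length(elig) == 0) stop("scenario error: empty eligible pool")
  if (is.null(ais_mix)) {
    return(sample(elig, n, replace = TRUE))
  }
  ais_mix <- ais_mix / sum(ais_mix)
  counts <- floor(n * ais_mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * ais_mix - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  idx <- integer(0)
  for (g in names(counts)) {
    if (counts[[g]] == 0) next
    strat <- elig[pool$ais[elig] == g]
    if (length(strat) == 0) stop("scenario error: no eligible AIS ", g,
                                 " patients in pool")
    idx <- c(idx, sample(strat, counts[[g]], replace = TRUE))
  }
  sample(idx)  # shuffle stratum order
}

#' Match a zero-treatment cohort to a control cohort
#'
#' Greedy sequential matching in random member order: for every control
#' member, candidates agreeing exactly on sex and AIS grade and within the
#' age and NLI tolerances are ranked by NLI proximity first and age
#' proximity second (random tie-break); the nearest unused candidate is
#' taken. Ranking the (discrete, outcome-relevant) injury level before age
#' keeps the matched cohort's level distribution centred on the control's,
#' which the segment-tolerance window alone does not guarantee near
#' region-density boundaries. Candidates are reused only if the
#' pool is exhausted for a member (with a warning). By default each member's
#' own patient is excluded from its candidates (`exclude = "self"`), which
#' prevents trivial self-matching while keeping rare covariate profiles
#' matchable; `exclude = "drawn"` additionally removes every instance drawn
#' into the control cohort, and `exclude = "none"` permits self-matches
#' (useful for degenerate-identity checks).
#'
#' @param pool An `sci_instances` pool.
#' @param control Integer row indices of the control cohort in `pool`.
#' @param tol An `sci_match_tol`.
#' @param exclude Candidate exclusion rule: `"self"` (default), `"drawn"`,
#'   or `"none"`.
#' @return Integer vector of matched pool row indices, aligned with
#'   `control`; errors if some member has no tolerance-satisfying candidate.
#' @export
match_zero_treatment <- function(pool, control, tol = match_tolerances(),
                                 exclude = c("self", "drawn", "none")) {
  exclude <- match.arg(exclude)
  cand <- seq_len(nrow(pool))
  if (exclude == "drawn") cand <- setdiff(cand, unique(control))
  if (length(cand) == 0) stop("matching-failure: empty candidate pool")
  age <- pool$age; sex <- pool$sex; ais <- pool$ais; nli <- pool$nli_index
  pid <- pool$patient_id
  used <- logical(nrow(pool))
  matched <- integer(length(control))
  order_members <- sample(seq_along(control))
  warned <- FALSE
  for (m in order_members) {
    i <- control[m]
    ok <- abs(age[cand] - age[i]) <= tol$age_years &
      abs(nli[cand] - nli[i]) <= tol$nli_segments
    if (tol$sex_exact) ok <- ok & sex[cand] == sex[i]
    if (tol$ais_exact) ok <- ok & ais[cand] == ais[i]
    if (exclude == "self") ok <- ok & pid[cand] != pid[i]
    elig <- cand[ok]
    if (length(elig) == 0) {
      stop(sprintf(
        "matching-failure: no candidate for member (age %.0f, %s, NLI index %d, AIS %s)",
        age[i], sex[i], nli[i], ais[i]))
    }
    free <- elig[!used[elig]]
    if (length(free) == 0) {
      if (!warned) {
        warning("candidate pool exhausted; reusing matched candidates")
        warned <- TRUE
      }
      free <- elig
    }
    nli_gap <- abs(nli[free] - nli[i])
    best <- free[nli_gap == min(nli_gap)]
    age_gap <- abs(age[best] - age[i])
    best <- best[age_gap == min(age_gap)]
    pick <- if (length(best) == 1) best else sample(best, 1)
    matched[m] <- pick
    used[pick] <- TRUE
  }
  matched
}

#' Run one trial replicate
#'
#' @param pool An `sci_instances` pool (one row per patient).
#' @param n Cohort size.
#' @param model An `sci_recovery_model` providing the synthetic control
#'   predictions; must be trained on data disjoint from `pool` (checked
#'   against the training manifest unless `check_disjoint = FALSE`, as for
#'   the reference `oracle` predictors which carry no training data).
#' @param ais_mix,plegia Cohort composition, see [draw_control()].
#' @param tol Matching tolerances.
#' @param check_disjoint Verify pool patients are absent from the model's
#'   training manifest (default TRUE for trained families).
#' @return List with `delta_randomized`, `delta_synthetic`, `control`,
#'   `zero_treatment` (row indices), and `tolerances_ok` (all matched pairs
#'   satisfy the tolerances; asserted per replicate).
#' @export
run_replicate <- function(pool, n, model, ais_mix = NULL, plegia = "both",
                          tol = match_tolerances(), exclude = "self",
                          check_disjoint = TRUE) {
  if (check_disjoint &&
      !model$spec$family %in% c("baseline", "oracle", "noisy_oracle") &&
      length(intersect(model$manifest$patients, pool$patient_id)) > 0) {
    stop("pool overlaps the model's training patients")
  }
  control <- draw_control(pool, n, ais_mix = ais_mix, plegia = plegia)
  zt <- match_zero_treatment(pool, control, tol = tol, exclude = exclude)
  ok <- abs(pool$age[zt] - pool$age[control]) <= tol$age_years &
    abs(pool$nli_index[zt] - pool$nli_index[control]) <= tol$nli_segments &
    (!tol$sex_exact | pool$sex[zt] == pool$sex[control]) &
    (!tol$ais_exact | pool$ais[zt] == pool$ais[control])
  ctrl_rows <- pool[control, , drop = FALSE]
  zt_rows <- pool[zt, , drop = FALSE]
  obs_ctrl <- mean(lems_improvement(ctrl_rows))
  obs_zt <- mean(lems_improvement(zt_rows))
  pred_late <- predict(model, zt_rows)
  pred_zt <- mean(lems_improvement(zt_rows, late = pred_late))
  list(delta_randomized = obs_zt - obs_ctrl,
       delta_synthetic = obs_zt - pred_zt,
       control = control, zero_treatment = zt,
       tolerances_ok = all(ok))
}

#' Repeat trial replicates
#'
#' Runs `n_trials` independent replicates with seeds derived from
#' `base_seed` and summarizes the two delta distributions.
#'
#' @inheritParams run_replicate
#' @param n_trials Number of replicates (default 500).
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @param restrict_support Apply [common_support()] to the pool once before
#'   simulating (default TRUE), so every drawn control is matchable.
#' @param absolute Compute percentile summaries on |delta| instead of the
#'   signed delta (default FALSE, the signed convention).
#' @return List of class `sci_sim_summary`: `replicates` data.frame (one row
#'   per replicate), `summary` data.frame (per control type: median,
#'   quartiles, 95th percentile, mean), `n_trials`, `failures`.
#' @export
repeat_trials <- function(pool, n, model, n_trials = 500L, base_seed = 1L,
                          ais_mix = NULL, plegia = "both",
                          tol = match_tolerances(), exclude = "self",
                          absolute = FALSE, check_disjoint = TRUE,
                          restrict_support = TRUE) {
  if (nrow(pool) == 0) stop("empty simulation pool")
  if (restrict_support) pool <- common_support(pool, tol)
  if (nrow(pool) == 0) stop("no pool patient has a tolerance-compatible partner")
  reps <- vector("list", n_trials)
  failures <- 0L
  for (r in seq_len(n_trials)) {
    reps[[r]] <- tryCatch(
      with_seed((base_seed + r) %% .Machine$integer.max,
                run_replicate(pool, n, model, ais_mix = ais_mix,
                              plegia = plegia, tol = tol, exclude = exclude,
                              check_disjoint = check_disjoint)),
      error = function(e) e)
    if (inherits(reps[[r]], "error")) failures <- failures + 1L
  }
  ok <- !vapply(reps, inherits, logical(1), "error")
  df <- data.frame(
    replicate = which(ok),
    delta_randomized = vapply(reps[ok], `[[`, numeric(1), "delta_randomized"),
    delta_synthetic = vapply(reps[ok], `[[`, numeric(1), "delta_synthetic"),
    tolerances_ok = vapply(reps[ok], `[[`, logical(1), "tolerances_ok"))
  summ <- function(x, label) {
    v <- if (absolute) abs(x) else x
    data.frame(control_type = label, mean = mean(x), median = stats::median(v),
               q25 = pct(v, 0.25), q75 = pct(v, 0.75), p95 = pct(v, 0.95),
               stringsAsFactors = FALSE)
  }
  structure(list(
    replicates = df,
    summary = rbind(summ(df$delta_randomized, "randomized"),
                    summ(df$delta_synthetic, "synthetic")),
    n_trials = n_trials, failures = failures,
    scenario = list(n = n, ais_mix = ais_mix, plegia = plegia)),
    class = "sci_sim_summary")
}

#' @export
print.sci_sim_summary <- function(x, ...) {
  cat(sprintf("<trial simulation: %d replicates (%d failed), cohort n=%d, plegia=%s>\n",
              x$n_trials, x$failures, x$scenario$n, x$scenario$plegia))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Scenario sweep of trial simulations
#'
#' Repeats the simulation over combinations of cohort size, AIS composition
#' and plegia and tabulates the 95th percentile of each delta distribution.
#'
#' @inheritParams repeat_trials
#' @param sizes Integer vector of cohort sizes.
#' @param ais_mixes Named list of AIS mixes (`NULL` entry = pool mix).
#' @param plegia_options Character vector from
#'   `c("both", "tetraplegia", "paraplegia")`.
#' @return List with `table` (tidy data.frame: scenario descriptors, control
#'   type, p95, median) and `summaries` (per-scenario `sci_sim_summary`).
#' @export
scenario_sweep <- function(pool, model, sizes = 200L,
                           ais_mixes = list(pool = NULL),
                           plegia_options = "both", n_trials = 500L,
                           base_seed = 1L, tol = match_tolerances(),
                           exclude = "self", absolute = FALSE,
                           check_disjoint = TRUE) {
  rows <- list(); sums <- list()
  sc <- 0L
  for (sz in sizes) for (mx in names(ais_mixes)) for (pl in plegia_options) {
    sc <- sc + 1L
    res <- tryCatch(
      repeat_trials(pool, sz, model, n_trials = n_trials,
                    base_seed = base_seed + 10000L * sc,
                    ais_mix = ais_mixes[[mx]], plegia = pl, tol = tol,
                    exclude = exclude, absolute = absolute,
                    check_disjoint = check_disjoint),
      error = function(e) e)
    key <- sprintf("n%d_%s_%s", sz, mx, pl)
    if (inherits(res, "error")) {
      rows[[key]] <- data.frame(size = sz, ais_mix = mx, plegia = pl,
                                control_type = NA, p95 = NA, median = NA,
                                error = conditionMessage(res))
      next
    }
    sums[[key]] <- res
    rows[[key]] <- data.frame(size = sz, ais_mix = mx, plegia = pl,
                              control_type = res$summary$control_type,
                              p95 = res$summary$p95,
                              median = res$summary$median, error = NA)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, summaries = sums)
}
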