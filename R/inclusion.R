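# Cohort inclusion filters and the instance table.
#
# An "instance" is one (early assessment, late assessment) training or
# evaluation pair of a single patient. Instances are stored as a wide
# data.frame (class sci_instances), one row per pair, which is the working
# container of the whole pipeline: columns are
#   patient_id, age, sex, ais, nli, nli_index, early_dai, late_dai, vac, dap,
#   ms_early_* (20), lt_early_* (56), pp_early_* (56), ms_late_* (20).

instance_row <- function(rec, early, late) {
  c(list(patient_id = rec$patient_id, age = rec$age_at_injury, sex = rec$sex,
         ais = early$ais, nli = early$nli,
         nli_index = level_index(early$nli),
         early_dai = early$dai, late_dai = late$dai,
         vac = as.integer(early$vac), dap = as.integer(early$dap)),
    as.list(stats::setNames(early$motor, paste0("ms_early_", names(early$motor)))),
    as.list(stats::setNames(early$light_touch,
                            paste0("lt_early_", names(early$light_touch)))),
    as.list(stats::setNames(early$pinprick,
                            paste0("pp_early_", names(early$pinprick)))),
    as.list(stats::setNames(late$motor, paste0("ms_late_", names(late$motor)))))
}

as_instances <- function(rows) {
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(nrow = 0, ncol = 0))
  } else {
    cols <- names(rows[[1L]])
    df <- as.data.frame(
      lapply(stats::setNames(cols, cols),
             function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  class(df) <- c("sci_instances", "data.frame")
  rownames(df) <- NULL
  df
}

ms_early_cols <- function() paste0("ms_early_", motor_coords())
ms_late_cols <- function() paste0("ms_late_", motor_coords())

#' Benchmark inclusion filter
#'
#' Builds the instance table used for model training and evaluation: every
#' (early, late) assessment pair of a patient with `early$dai <=
#' early_max_dai`, `late$dai >= late_min_dai`, AIS grade A-D, NLI rostral to
#' S1, and no motor deterioration of two or more points between the two
#' assessments. Patients with several qualifying assessments contribute
#' multiple instances.
#'
#' Applied to an existing instance table, the same predicate filters its
#' rows, so the operation is idempotent on its own output.
#'
#' @param x A list of `sci_patient` records, an `sci_cohort`, or an
#'   `sci_instances` table.
#' @param early_max_dai Latest allowed day for the early assessment
#'   (default 98).
#' @param late_min_dai Earliest allowed day for the late assessment
#'   (default 150).
#' @return An `sci_instances` data.frame (possibly zero rows).
#' @export
benchmark_inclusion <- function(x, early_max_dai = 98L, late_min_dai = 150L) {
  stopifnot(early_max_dai < late_min_dai)
  if (inherits(x, "sci_cohort")) x <- x$records
  if (inherits(x, "sci_instances")) {
    keep <- x$early_dai <= early_max_dai & x$late_dai >= late_min_dai &
      x$ais %in% c("A", "B", "C", "D") & x$nli_index < level_index("S1")
    e <- as.matrix(x[, ms_early_cols(), drop = FALSE])
    l <- as.matrix(x[, ms_late_cols(), drop = FALSE])
    keep <- keep & apply(l - e, 1, function(d) !any(d <= -2))
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  rows <- list()
  for (rec in x) {
    as <- rec$assessments
    dais <- vapply(as, `[[`, integer(1), "dai")
    for (i in which(dais <= early_max_dai)) {
      early <- as[[i]]
      if (!early$ais %in% c("A", "B", "C", "D")) next
      if (level_index(early$nli) >= level_index("S1")) next
      for (j in which(dais >= late_min_dai)) {
        late <- as[[j]]
        if (late$dai <= early$dai) next
        if (deterioration_flag(early, late)) next
        rows[[length(rows) + 1L]] <- instance_row(rec, early, late)
      }
    }
  }
  as_instances(rows)
}

#' Case-study inclusion filter (cervical single-arm endpoint)
#'
#' Keeps instances mirroring the inclusion criteria of a recent cervical SCI
#' trial endpoint: cervical NLI (C2-C8), baseline assessment within 28 DAI,
#' follow-up at 168 +/- 7 DAI, and baseline UEMS below 29 points.
#'
#' @param instances An `sci_instances` table.
#' @return The filtered `sci_instances` table.
#' @export
nisci_inclusion <- function(instances) {
  stopifnot(inherits(instances, "sci_instances"))
  base_uems <- uems(stats::setNames(
    instances[, paste0("ms_early_", motor_coords()), drop = FALSE],
    motor_coords()))
  keep <- instances$nli_index <= level_index("C8") &
    instances$early_dai <= 28L &
    instances$late_dai >= 161L & instances$late_dai <= 175L &
    base_uems < 29
  out <- instances[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-patient trial-simulation pool: one instance per patient, built from the
# earliest assessment (required <= early_max_dai, default 40) and the latest
# available assessment, under the same exclusions as benchmark_inclusion.
#' Trial-simulation pool
#'
#' One instance per patient for the trial simulations: earliest assessment
#' (at most `early_max_dai` days after injury, default 40) as baseline and
#' the latest available assessment as follow-up, with the standard
#' exclusions (AIS A-D, NLI rostral to S1, no >= 2-point motor
#' deterioration).
#'
#' @param x A list of `sci_patient` records or an `sci_cohort`.
#' @param early_max_dai Latest allowed baseline day (default 40).
#' @return An `sci_instances` table with one row per eligible patient.
#' @export
trial_pool <- function(x, early_max_dai = 40L) {
  if (inherits(x, "sci_cohort")) x <- x$records
  rows <- list()
  for (rec in x) {
    as <- rec$assessments
    dais <- vapply(as, `[[`, integer(1), "dai")
    if (length(as) < 2L) next
    early <- as[[which.min(dais)]]
    late <- as[[which.max(dais)]]
    if (early$dai > early_max_dai || late$dai <= early$dai) next
    if (!early$ais %in% c("A", "B", "C", "D")) next
    if (level_index(early$nli) >= level_index("S1")) next
    if (deterioration_flag(early, late)) next
    rows[[length(rows) + 1L]] <- instance_row(rec, early, late)
  }
  as_instances(rows)
}

# Observed LEMS / UEMS improvement per instance row.
lems_improvement <- function(instances, late = NULL) {
  e <- as.matrix(instances[, ms_early_cols(), drop = FALSE])
  colnames(e) <- motor_coords()
  l <- if (is.null(late)) {
    m <- as.matrix(instances[, ms_late_cols(), drop = FALSE])
    colnames(m) <- motor_coords()
    m
  } else late
  lems(l) - lems(e)
}

uems_improvement <- function(instances, late = NULL) {
  e <- as.matrix(instances[, ms_early_cols(), drop = FALSE])
  colnames(e) <- motor_coords()
  l <- if (is.null(late)) {
    m <- as.matrix(instances[, ms_late_cols(), drop = FALSE])
    colnames(m) <- motor_coords()
    m
  } else late
  uems(l) - uems(e)
}
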