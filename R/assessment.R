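# Assessment and patient-record containers.
#
# An assessment is a full ISNCSCI examination at one time point: 20 key-muscle
# motor scores (0-5), 56 light-touch and 56 pinprick scores (0-2), the binary
# sacral indicators VAC and DAP, the AIS grade and the NLI. AIS and NLI are
# consumed as given; the package never re-derives them from the scores.

AIS_GRADES <- c("A", "B", "C", "D", "E")

#' Construct an ISNCSCI assessment
#'
#' @param patient_id Opaque patient identifier.
#' @param dai Days after injury (non-negative integer).
#' @param motor Named numeric vector: the 20 key-muscle scores in 0-5, names
#'   as in [motor_coords()].
#' @param light_touch,pinprick Named numeric vectors: 56 scores in 0-2,
#'   names as `<level>_<side>` over all 28 levels.
#' @param vac,dap Logical (or 0/1): voluntary anal contraction / deep anal
#'   pressure present.
#' @param ais AIS grade, one of `"A"`..`"E"`.
#' @param nli Neurological level of injury, a level label.
#' @return An object of class `sci_assessment`.
#' @export
new_assessment <- function(patient_id, dai, motor, light_touch, pinprick,
                           vac, dap, ais, nli) {
  a <- structure(
    list(patient_id = patient_id, dai = as.integer(dai),
         motor = motor[motor_coords()],
         light_touch = light_touch[sensory_coords()],
         pinprick = pinprick[sensory_coords()],
         vac = as.logical(vac), dap = as.logical(dap),
         ais = ais, nli = nli),
    class = "sci_assessment")
  names(a$motor) <- motor_coords()
  names(a$light_touch) <- sensory_coords()
  names(a$pinprick) <- sensory_coords()
  validate_assessment(a)
}

#' Validate an assessment
#'
#' Checks completeness and score bounds: all 20 motor entries in \[0,5\],
#' all 56 entries per sensory modality in \[0,2\], `dai >= 0`, known AIS
#' grade and NLI.
#'
#' @param a An `sci_assessment`.
#' @return `a`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_assessment <- function(a) {
  stopifnot(inherits(a, "sci_assessment"))
  if (is.na(a$dai) || a$dai < 0L) stop("invalid assessment: dai must be >= 0")
  if (anyNA(a$motor) || any(a$motor < 0 | a$motor > 5)) {
    stop("invalid assessment: motor scores must be complete and in [0, 5]")
  }
  for (mod in c("light_touch", "pinprick")) {
    s <- a[[mod]]
    if (anyNA(s) || any(s < 0 | s > 2)) {
      stop("invalid assessment: ", mod, " scores must be complete and in [0, 2]")
    }
  }
  if (!a$ais %in% AIS_GRADES) stop("invalid assessment: unknown AIS grade")
  level_index(a$nli)
  invisible(a)
}

#' @export
print.sci_assessment <- function(x, ...) {
  cat(sprintf("<ISNCSCI assessment: patient %s, %d DAI, AIS %s, NLI %s, UEMS %d, LEMS %d>\n",
              x$patient_id, x$dai, x$ais, x$nli, uems(x), lems(x)))
  invisible(x)
}

motor_sum <- function(x, levels) {
  coords <- as.vector(t(outer(levels, SIDES, paste, sep = "_")))
  if (inherits(x, "sci_assessment")) x <- x$motor
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x[, coords, drop = FALSE])
    if (anyNA(m)) stop("invalid assessment: missing motor entry")
    return(rowSums(m))
  }
  v <- x[coords]
  if (anyNA(v)) stop("invalid assessment: missing motor entry")
  sum(v)
}

#' Upper extremity motor score
#'
#' Sum of the 10 key-muscle motor scores at C5-T1, both sides; range 0-50.
#'
#' @param x An `sci_assessment`, a named motor-score vector, or a
#'   matrix/data.frame with the 20 motor coordinate columns (one row per
#'   assessment).
#' @return Numeric score(s) in \[0, 50\].
#' @export
uems <- function(x) motor_sum(x, UEMS_LEVELS)

#' Lower extremity motor score
#'
#' Sum of the 10 key-muscle motor scores at L2-S1, both sides; range 0-50.
#'
#' @inheritParams uems
#' @return Numeric score(s) in \[0, 50\].
#' @export
lems <- function(x) motor_sum(x, LEMS_LEVELS)

#' Motor-score deterioration flag
#'
#' TRUE iff any of the 20 motor coordinates dropped by two or more points
#' between the early and late assessment. Patients flagged here are excluded
#' from all analyses: observational registries do not record the
#' complications that drive such deterioration, so it cannot be modelled.
#'
#' @param early,late Paired `sci_assessment`s (or named motor vectors) of one
#'   patient.
#' @return Logical scalar.
#' @export
deterioration_flag <- function(early, late) {
  e <- if (inherits(early, "sci_assessment")) early$motor else early[motor_coords()]
  l <- if (inherits(late, "sci_assessment")) late$motor else late[motor_coords()]
  any(l - e <= -2)
}

#' Construct a patient record
#'
#' @param patient_id Identifier shared by all assessments.
#' @param age_at_injury Age in years (> 0).
#' @param sex `"female"` or `"male"`.
#' @param assessments List of `sci_assessment`, strictly increasing in `dai`.
#' @return An object of class `sci_patient`.
#' @export
new_patient_record <- function(patient_id, age_at_injury, sex, assessments) {
  stopifnot(age_at_injury > 0, sex %in% c("female", "male"))
  dais <- vapply(assessments, `[[`, integer(1), "dai")
  if (length(dais) > 1 && any(diff(dais) <= 0)) {
    stop("assessments must be strictly increasing in dai")
  }
  ids <- vapply(assessments, `[[`, character(1), "patient_id")
  if (!all(ids == patient_id)) stop("assessment patient_id mismatch")
  structure(list(patient_id = patient_id, age_at_injury = age_at_injury,
                 sex = sex, assessments = assessments),
            class = "sci_patient")
}

#' @export
print.sci_patient <- function(x, ...) {
  cat(sprintf("<patient %s: %s, age %.0f, %d assessments at DAI %s>\n",
              x$patient_id, x$sex, x$age_at_injury, length(x$assessments),
              paste(vapply(x$assessments, `[[`, integer(1), "dai"),
                    collapse = ", ")))
  invisible(x)
}
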