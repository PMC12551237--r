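# Shared fixtures, built in code.

# A valid assessment with every motor score `motor_fill`, every sensory
# score `sens_fill`; individual scores overridable by name.
make_assessment <- function(patient_id = "P1", dai = 10, motor_fill = 0,
                            sens_fill = 0, motor = c(), ais = "B",
                            nli = "C5", vac = FALSE, dap = TRUE) {
  m <- stats::setNames(rep(motor_fill, 20), motor_coords())
  m[names(motor)] <- motor
  s <- stats::setNames(rep(sens_fill, 56), sctsim:::sensory_coords())
  new_assessment(patient_id, dai, m, s, s, vac, dap, ais, nli)
}

make_patient <- function(patient_id = "P1", age = 40, sex = "male",
                         dais = c(14, 180), ...) {
  asmts <- lapply(dais, function(d) make_assessment(patient_id, dai = d, ...))
  new_patient_record(patient_id, age, sex, asmts)
}

# Session-cached synthetic cohorts (generation is deterministic, caching is
# purely a speed optimization).
.fixture_env <- new.env()

test_cohort <- function(n = 300, seed = 42) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(default_emsci_config(n_patients = n,
                                                                seed = seed))
  }
  .fixture_env[[key]]
}

test_instances <- function(n = 300, seed = 42) {
  key <- sprintf("inst_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- benchmark_inclusion(test_cohort(n, seed))
  }
  .fixture_env[[key]]
}

test_pool <- function(n = 2000, seed = 42) {
  key <- sprintf("pool_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- common_support(trial_pool(test_cohort(n, seed)))
  }
  .fixture_env[[key]]
}

# The 10-patient crafted filter fixture: 5 clean patients, 3 with an
# engineered >= 2-point deterioration, 1 AIS E, 1 with NLI at S2.
filter_fixture <- function() {
  clean <- lapply(1:5, function(i) {
    make_patient(sprintf("OK%d", i), motor_fill = 2, ais = "B", nli = "C5")
  })
  det <- lapply(1:3, function(i) {
    early <- make_assessment(sprintf("DET%d", i), dai = 14, motor_fill = 3,
                             ais = "C", nli = "C6")
    late_m <- stats::setNames(rep(3, 20), motor_coords())
    late_m["L3_left"] <- 1  # two-point drop
    late <- make_assessment(sprintf("DET%d", i), dai = 180, motor_fill = 3,
                            motor = late_m["L3_left"], ais = "C", nli = "C6")
    new_patient_record(sprintf("DET%d", i), 35, "female",
                       list(early, late))
  })
  ais_e <- list(make_patient("AISE", motor_fill = 5, sens_fill = 2, ais = "E",
                             nli = "C5"))
  sacral <- list(make_patient("SAC", motor_fill = 4, ais = "D", nli = "S2"))
  c(clean, det, ais_e, sacral)
}
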