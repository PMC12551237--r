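test_that("matching eligibility honours every tolerance", {
  mk_row <- function(id, age, sex, nli, ais) {
    p <- make_patient(id, age = age, sex = sex, motor_fill = 2, ais = ais,
                      nli = nli)
    benchmark_inclusion(list(p))
  }
  pool <- rbind(mk_row("ctrl", 50, "female", "C5", "B"),
                mk_row("ok", 54, "female", "C7", "B"),
                mk_row("age6", 56, "female", "C5", "B"),
                mk_row("man", 50, "male", "C5", "B"),
                mk_row("far", 50, "female", "T1", "B"),
                mk_row("aisC", 50, "female", "C5", "C"))
  class(pool) <- c("sci_instances", "data.frame")
  set.seed(1)
  m <- match_zero_treatment(pool, control = 1L)
  expect_equal(pool$patient_id[m], "ok")  # the only eligible candidate
  # with the eligible candidate removed, matching fails naming the member
  expect_error(match_zero_treatment(pool[-2, ], control = 1L),
               "matching-failure")
})

test_that("control draws honour replacement, composition, and determinism", {
  pool <- test_pool(2000)
  set.seed(3)
  idx <- draw_control(pool, 300, ais_mix = NULL)
  expect_length(idx, 300)
  set.seed(3)
  expect_identical(idx, draw_control(pool, 300, ais_mix = NULL))
  # pure-AIS-A composition
  set.seed(4)
  idx_a <- draw_control(pool, 100, ais_mix = c(A = 1, B = 0, C = 0, D = 0))
  expect_true(all(pool$ais[idx_a] == "A"))
  # more draws than distinct pool members is fine (with replacement)
  small <- pool[1:50, ]
  set.seed(5)
  expect_length(draw_control(small, 200), 200)
  # plegia filters restrict the eligible levels
  set.seed(6)
  idx_t <- draw_control(pool, 100, plegia = "tetraplegia")
  expect_true(all(pool$nli_index[idx_t] <= level_index("C8")))
})

test_that("an oracle predictor gives a synthetic delta of exactly zero", {
  pool <- test_pool(2000)
  m <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  set.seed(11)
  r <- run_replicate(pool, 100, m)
  expect_identical(r$delta_synthetic, 0)
  expect_true(r$tolerances_ok)
})

test_that("self-matching with zero tolerances gives a randomized delta of zero", {
  pool <- test_pool(2000)[1:200, ]
  pool$age <- seq_len(nrow(pool))  # unique ages force self-matches
  m <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  set.seed(2)
  ctrl <- draw_control(pool, 50)
  zt <- suppressWarnings(
    match_zero_treatment(pool, ctrl,
                         tol = match_tolerances(age_years = 0,
                                                nli_segments = 0),
                         exclude = "none"))
  expect_equal(zt, ctrl)
  obs_c <- mean(sctsim:::lems_improvement(pool[ctrl, ]))
  obs_z <- mean(sctsim:::lems_improvement(pool[zt, ]))
  expect_equal(obs_z - obs_c, 0)
})

test_that("a constant caudal bias appears as -10k in the synthetic delta", {
  # cervical/thoracic patients: all 10 lumbosacral myotomes lie below the NLI
  pool <- test_pool(2000)
  pool <- common_support(pool[pool$nli_index <= level_index("T10"), ])
  k <- 0.3
  oracle <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  biased_predict <- function(rows) {
    p <- predict(oracle, rows)
    lumbo <- as.vector(t(outer(c("L2", "L3", "L4", "L5", "S1"),
                               c("left", "right"), paste, sep = "_")))
    p[, lumbo] <- pmin(p[, lumbo] + k, 5)
    p
  }
  set.seed(13)
  ctrl <- draw_control(pool, 80)
  zt <- match_zero_treatment(pool, ctrl)
  zt_rows <- pool[zt, ]
  # keep away from the clipping boundary so the bias is exactly additive
  sat <- apply(sctsim:::target_matrix(zt_rows)[,
    paste0(rep(c("L2", "L3", "L4", "L5", "S1"), each = 2),
           "_", c("left", "right"))] > 5 - k, 1, any)
  zt_rows <- zt_rows[!sat, , drop = FALSE]
  obs <- mean(sctsim:::lems_improvement(zt_rows))
  pred <- mean(sctsim:::lems_improvement(zt_rows,
                                         late = biased_predict(zt_rows)))
  expect_equal(obs - pred, -10 * k, tolerance = 1e-10)
})

test_that("repeated trials are deterministic and tolerance-clean", {
  pool <- test_pool(2000)
  m <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  s1 <- suppressWarnings(repeat_trials(pool, 60, m, n_trials = 25,
                                       base_seed = 21))
  s2 <- suppressWarnings(repeat_trials(pool, 60, m, n_trials = 25,
                                       base_seed = 21))
  expect_identical(s1$replicates, s2$replicates)
  expect_equal(s1$failures, 0)
  expect_true(all(s1$replicates$tolerances_ok))
  expect_true(all(s1$replicates$delta_synthetic == 0))
  expect_equal(nrow(s1$replicates), 25)
})

test_that("an injected constant treatment effect shifts both deltas by tau", {
  pool <- test_pool(2000)
  m <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  tau <- 2.5
  set.seed(31)
  r <- run_replicate(pool, 80, m)
  # adding tau to each zero-treatment member's observed LEMS improvement
  zt_rows <- pool[r$zero_treatment, ]
  ctrl_rows <- pool[r$control, ]
  d_rand <- mean(sctsim:::lems_improvement(zt_rows) + tau) -
    mean(sctsim:::lems_improvement(ctrl_rows))
  d_syn <- mean(sctsim:::lems_improvement(zt_rows) + tau) -
    mean(sctsim:::lems_improvement(zt_rows,
                                   late = predict(m, zt_rows)))
  expect_equal(d_rand, r$delta_randomized + tau)
  expect_equal(d_syn, r$delta_synthetic + tau)
})

test_that("randomized delta spread shrinks with cohort size", {
  pool <- test_pool(2000)
  m <- fit_recovery_model(model_spec("oracle"), pool[1:5, ])
  s_small <- suppressWarnings(repeat_trials(pool, 50, m, n_trials = 60,
                                            base_seed = 41))
  s_large <- suppressWarnings(repeat_trials(pool, 400, m, n_trials = 60,
                                            base_seed = 41))
  expect_gt(sd(s_small$replicates$delta_randomized),
            sd(s_large$replicates$delta_randomized))
})

test_that("scenario sweeps tabulate one P95 row per control type", {
  pool <- test_pool(2000)
  m <- fit_recovery_model(model_spec("noisy_oracle", list(sd = 0.5), seed = 1),
                          pool[1:5, ])
  sw <- suppressWarnings(
    scenario_sweep(pool, m, sizes = c(60), n_trials = 20, base_seed = 51))
  expect_equal(nrow(sw$table), 2)
  expect_setequal(sw$table$control_type, c("randomized", "synthetic"))
  expect_true(all(is.finite(sw$table$p95)))
})
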