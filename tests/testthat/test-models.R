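test_that("encoding is deterministic, ordered, and leaks no target", {
  inst <- test_instances(100)
  X1 <- encode_instances(inst)
  X2 <- encode_instances(inst)
  expect_identical(X1, X2)
  expect_equal(ncol(X1), 71)  # 60 sequence + 11 scalar features
  expect_equal(colnames(X1)[1:3], c("ms_C5_left", "lt_C5_left", "pp_C5_left"))
  # altering late motor scores leaves the encoding unchanged
  mod <- inst
  mod[, paste0("ms_late_", motor_coords())] <- 0
  expect_identical(X1, encode_instances(mod))
  # changing only the NLI changes exactly one (scalar) feature column
  mod2 <- inst
  mod2$nli_index <- mod2$nli_index + 1L
  d <- which(colSums(encode_instances(mod2) != X1) > 0)
  expect_equal(names(d), "nli_index")
})

test_that("a constant-target linear fit returns that constant", {
  inst <- test_instances(60)
  const <- inst
  const[, paste0("ms_late_", motor_coords())] <- 3
  m <- fit_recovery_model(model_spec("linear_regularized", seed = 1), const)
  p <- predict(m, const)
  expect_lt(max(abs(p - 3)), 1e-6)
})

test_that("fitting refuses a single-patient training set", {
  inst <- test_instances(60)
  one <- inst[inst$patient_id == inst$patient_id[1], , drop = FALSE]
  expect_error(fit_recovery_model(model_spec("linear_regularized"), one),
               "degenerate")
})

test_that("training is seed-reproducible and row-order invariant", {
  inst <- test_instances(100)
  probe <- test_instances(100)[1:20, ]
  for (fam in c("linear_regularized", "conv_sequence")) {
    hyperp <- if (fam == "conv_sequence") list(epochs = 5L) else list()
    m1 <- fit_recovery_model(model_spec(fam, hyperp, seed = 7), inst)
    m2 <- fit_recovery_model(model_spec(fam, hyperp, seed = 7), inst)
    expect_equal(predict(m1, probe), predict(m2, probe), tolerance = 1e-12)
    shuf <- inst[rev(seq_len(nrow(inst))), ]
    m3 <- fit_recovery_model(model_spec(fam, hyperp, seed = 7), shuf)
    expect_equal(predict(m1, probe), predict(m3, probe), tolerance = 1e-12)
  }
})

test_that("every family runs end-to-end and respects the score range", {
  inst <- test_instances(100)
  folds <- cv_folds(inst$patient_id, 5, 1)
  tr <- inst[folds != 1, ]
  te <- inst[folds == 1, ]
  fams <- c("linear_regularized", "random_forest", "gradient_boosted_trees",
            "conv_sequence", "seq2seq_attention", "graph_sequence", "baseline")
  for (fam in fams) {
    hyperp <- if (fam %in% c("conv_sequence", "seq2seq_attention",
                             "graph_sequence")) list(epochs = 8L) else list()
    m <- fit_recovery_model(model_spec(fam, hyperp, seed = 2), tr)
    p <- predict(m, te)
    expect_equal(dim(p), c(nrow(te), 20))
    expect_true(all(p >= 0 & p <= 5), info = fam)
  }
})

test_that("neural training loss decreases from first to final epoch", {
  inst <- test_instances(300)
  for (fam in c("conv_sequence", "seq2seq_attention", "graph_sequence")) {
    m <- fit_recovery_model(model_spec(fam, list(epochs = 15L), seed = 4), inst)
    lc <- m$fit$loss_curve
    expect_length(lc, 15)
    expect_lt(lc[length(lc)], lc[1])
  }
})

test_that("reference predictors implement their defining identities", {
  inst <- test_instances(100)[1:30, ]
  oracle <- fit_recovery_model(model_spec("oracle"), inst)
  expect_equal(predict(oracle, inst),
               sctsim:::target_matrix(inst))
  base <- fit_recovery_model(model_spec("baseline"), inst)
  obs_early <- as.matrix(inst[, paste0("ms_early_", motor_coords())])
  expect_equal(unname(predict(base, inst)), unname(obs_early))
  # the carry-forward null scores exactly as a no-recovery prediction
  e <- instance_errors(predict(base, inst), inst)
  manual <- vapply(seq_len(nrow(inst)), function(i) {
    co <- myotomes_below_nli(inst$nli[i])
    sqrt(mean((obs_early[i, match(co, motor_coords())] -
                 sctsim:::target_matrix(inst)[i, co])^2))
  }, numeric(1))
  expect_equal(e$rmse_bl_nli, manual)
})

test_that("noisy oracle is unbiased, patient-deterministic noise", {
  inst <- test_instances(100)
  m <- fit_recovery_model(model_spec("noisy_oracle", list(sd = 0.5), seed = 3),
                          inst[1:5, ])
  p1 <- predict(m, inst)
  p2 <- predict(m, inst)
  expect_identical(p1, p2)
  resid <- p1 - sctsim:::target_matrix(inst)
  interior <- sctsim:::target_matrix(inst) > 0.5 &
    sctsim:::target_matrix(inst) < 4.5
  expect_lt(abs(mean(resid[interior])), 0.1)
})

test_that("schema mismatches are rejected at prediction time", {
  inst <- test_instances(60)
  m <- fit_recovery_model(model_spec("linear_regularized", seed = 1), inst)
  m$manifest$schema <- "sctsim-enc-0"
  expect_error(predict(m, inst), "schema")
})

test_that("model persistence round-trips through a directory", {
  inst <- test_instances(60)
  m <- fit_recovery_model(model_spec("conv_sequence", list(epochs = 3L),
                                     seed = 5), inst)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(predict(m, inst[1:10, ]), predict(m2, inst[1:10, ]))
  expect_equal(m2$spec$family, "conv_sequence")
})

test_that("perturbation bands bracket the point prediction", {
  inst <- test_instances(60)[1:15, ]
  m <- fit_recovery_model(model_spec("linear_regularized", seed = 1),
                          test_instances(60))
  pb <- perturb_predict(m, inst, n_reps = 20, perturb_prob = 0.15, seed = 8)
  expect_true(all(pb$lower <= pb$point + 1e-12))
  expect_true(all(pb$point <= pb$upper + 1e-12))
  # zero perturbation probability collapses the band onto the point
  pb0 <- perturb_predict(m, inst, n_reps = 10, perturb_prob = 0, seed = 8)
  expect_equal(pb0$lower, pb0$point)
  expect_equal(pb0$upper, pb0$point)
  # reproducibility
  pb2 <- perturb_predict(m, inst, n_reps = 20, perturb_prob = 0.15, seed = 8)
  expect_identical(pb$lower, pb2$lower)
})
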