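# Independent brute-force oracle for the below-NLI metrics: an explicit
# loop over levels and sides, sharing no code with the package functions.
brute_below_nli <- function(pred, obs, nli) {
  keys <- c("C5", "C6", "C7", "C8", "T1", "L2", "L3", "L4", "L5", "S1")
  nli_i <- which(spinal_levels()$label == nli) - 1
  res <- c()
  for (k in keys) {
    k_i <- which(spinal_levels()$label == k) - 1
    if (k_i > nli_i) {
      for (s in c("left", "right")) {
        res <- c(res, pred[paste0(k, "_", s)] - obs[paste0(k, "_", s)])
      }
    }
  }
  list(rmse = sqrt(mean(res^2)), mean_resid = mean(res))
}

test_that("below-NLI metrics match a brute-force loop to 1e-12", {
  set.seed(101)
  nlis <- spinal_levels()$label[1:24]  # rostral to S1
  for (i in 1:300) {
    pred <- stats::setNames(runif(20, 0, 5), motor_coords())
    obs <- stats::setNames(sample(0:5, 20, replace = TRUE), motor_coords())
    nli <- sample(nlis, 1)
    bf <- brute_below_nli(pred, obs, nli)
    expect_equal(rmse_bl_nli(pred, obs, nli), bf$rmse, tolerance = 1e-12)
    expect_equal(mean_residual_bl_nli(pred, obs, nli), bf$mean_resid,
                 tolerance = 1e-12)
  }
})

test_that("worked below-NLI error cases reproduce", {
  obs <- stats::setNames(rep(2, 20), motor_coords())
  # NLI C6: 16 coordinates; unit residual at 4 of them -> sqrt(4/16) = 0.5
  pred <- obs
  pred[c("C7_left", "C8_left", "L2_right", "S1_right")] <- 3
  expect_equal(rmse_bl_nli(pred, obs, "C6"), 0.5)
  expect_equal(mean_residual_bl_nli(pred, obs, "C6"), 4 / 16)
  # NLI T6: 10 coordinates; one residual of 2 -> sqrt(4/10)
  pred2 <- obs
  pred2["L4_left"] <- 4
  expect_equal(rmse_bl_nli(pred2, obs, "T6"), sqrt(4 / 10))
  # identity
  expect_equal(rmse_bl_nli(obs, obs, "C6"), 0)
  expect_equal(mean_residual_bl_nli(obs, obs, "T6"), 0)
  # balanced residuals cancel in the mean but not the RMSE
  pred3 <- obs
  pred3["L2_left"] <- 3; pred3["L2_right"] <- 1
  expect_equal(mean_residual_bl_nli(pred3, obs, "T6"), 0)
  expect_gt(rmse_bl_nli(pred3, obs, "T6"), 0)
})

test_that("an oracle predictor yields an all-zero benchmark summary", {
  inst <- test_instances(100)
  m <- fit_recovery_model(model_spec("oracle"), inst[1:5, ])
  e <- instance_errors(predict(m, inst), inst)
  expect_true(all(e$rmse_bl_nli == 0))
  s <- summarize_errors(e)
  expect_true(all(s$rmse_median == 0 & s$rmse_p2.5 == 0 & s$rmse_p97.5 == 0))
})

test_that("summaries are permutation-invariant with ordered percentiles", {
  inst <- test_instances(100)
  m <- fit_recovery_model(model_spec("baseline"), inst[1:5, ])
  e <- instance_errors(predict(m, inst), inst)
  s1 <- summarize_errors(e)
  s2 <- summarize_errors(e[sample(nrow(e)), ])
  expect_equal(s1, s2)
  expect_true(all(s1$rmse_p2.5 <= s1$rmse_median))
  expect_true(all(s1$rmse_median <= s1$rmse_p97.5))
  # single error: all three statistics coincide
  s3 <- summarize_errors(e[1, , drop = FALSE])
  expect_equal(s3$rmse_median[1], e$rmse_bl_nli[1])
  expect_equal(s3$rmse_p2.5[1], e$rmse_bl_nli[1])
  # 0..100 has median 50
  ee <- e[rep(1, 101), ]
  ee$rmse_bl_nli <- 0:100
  expect_equal(summarize_errors(ee)$rmse_median[1], 50)
})

test_that("time profiles roll daily medians over a 7-day window", {
  e <- data.frame(early_dai = rep(1:20, each = 3), rmse_bl_nli = 1)
  tp <- time_profile(e)
  expect_true(all(tp$rolling_mean == 1))
  # linearly decreasing errors give a non-increasing curve
  e2 <- data.frame(early_dai = rep(1:20, each = 2),
                   rmse_bl_nli = rep(20:1, each = 2))
  tp2 <- time_profile(e2)
  expect_true(all(diff(tp2$rolling_mean) <= 0))
  # single day of data: curve defined at that day only
  e3 <- data.frame(early_dai = c(7, 7, 7), rmse_bl_nli = c(1, 2, 3))
  tp3 <- time_profile(e3)
  expect_equal(tp3$day, 7)
  expect_equal(tp3$daily_median, 2)
})

test_that("permutation importance finds signal and ignores constants", {
  inst <- test_instances(300)
  m <- fit_recovery_model(model_spec("linear_regularized", seed = 1), inst)
  imp <- feature_importance(m, inst[1:80, ], endpoint = "L3_left",
                            n_perm = 2, seed = 3)
  expect_equal(attr(imp, "backend"), "permutation")
  expect_equal(sort(imp$rank), seq_len(nrow(imp)))
  # constant features carry no importance
  const_feats <- imp$feature[c(grep("ais_", imp$feature))]
  probe <- inst[1:80, ]
  probe$ais <- "B"  # make AIS constant in the probe set
  imp2 <- feature_importance(m, probe, endpoint = "L3_left", n_perm = 2,
                             seed = 3)
  expect_true(all(abs(imp2$score[grep("^ais_", imp2$feature)]) < 1e-10))
})

test_that("a model blind to sensory inputs gets zero sensory importance", {
  inst <- test_instances(200)
  m <- fit_recovery_model(model_spec("baseline"), inst[1:5, ])
  imp <- feature_importance(m, inst[1:60, ], endpoint = "L3_left",
                            n_perm = 2, seed = 3)
  sens <- grepl("^(lt|pp)_", imp$feature)
  expect_true(all(abs(imp$score[sens]) < 1e-10))
  # carry-forward depends on its own coordinate only
  expect_gt(imp$score[imp$feature == "ms_L3_left"], 0)
  expect_true(all(abs(imp$score[imp$feature %in%
                                  c("ms_C5_left", "ms_S1_right")]) < 1e-10))
})

test_that("distance aggregation partitions sequence features", {
  inst <- test_instances(200)
  m <- fit_recovery_model(model_spec("linear_regularized", seed = 1), inst)
  imp <- feature_importance(m, inst[1:50, ], endpoint = "L3_left",
                            n_perm = 1, seed = 2)
  agg <- aggregate_by_distance(imp)
  seq_cells <- agg[agg$laterality != "scalar", ]
  expect_equal(sum(seq_cells$n_features), 60)
  expect_true(0 %in% seq_cells$distance)
  ep_cell <- seq_cells[seq_cells$distance == 0 &
                         seq_cells$laterality == "ipsilateral" &
                         seq_cells$modality == "MS", ]
  expect_equal(nrow(ep_cell), 1)
  scalars <- agg[agg$laterality == "scalar", ]
  expect_equal(nrow(scalars), 11)
})
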