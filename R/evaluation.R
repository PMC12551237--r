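# Benchmark metrics and stratified summaries.
#
# All segmental prediction errors are restricted to the key myotomes
# strictly caudal to the initial NLI, which makes errors comparable across
# patients regardless of lesion level.

below_nli_values <- function(x, nli) {
  coords <- myotomes_below_nli(nli)
  if (is.matrix(x) || is.data.frame(x)) x <- drop(as.matrix(x))
  v <- x[coords]
  if (anyNA(v)) stop("missing coordinate value below the NLI")
  v
}

#' RMSE of segmental motor scores below the NLI
#'
#' Root mean squared error between predicted and observed motor scores over
#' the key myotomes strictly caudal to `nli`, both sides.
#'
#' @param pred Named numeric vector (or 1-row matrix) of predicted motor
#'   scores over [motor_coords()].
#' @param obs Observed scores, same format, or an `sci_assessment`.
#' @param nli NLI level label (rostral to S1).
#' @return Non-negative scalar; 0 iff all below-NLI residuals are 0.
#' @export
#' @examples
#' p <- o <- stats::setNames(rep(2, 20), motor_coords())
#' rmse_bl_nli(p, o, "C6") # 0
rmse_bl_nli <- function(pred, obs, nli) {
  if (inherits(obs, "sci_assessment")) obs <- obs$motor
  r <- below_nli_values(pred, nli) - below_nli_values(obs, nli)
  sqrt(mean(r^2))
}

#' Mean residual of segmental motor scores below the NLI
#'
#' Mean of (predicted - observed) over the below-NLI key myotomes; positive
#' values mean systematic overestimation of recovery.
#'
#' @inheritParams rmse_bl_nli
#' @return Signed scalar.
#' @export
mean_residual_bl_nli <- function(pred, obs, nli) {
  if (inherits(obs, "sci_assessment")) obs <- obs$motor
  r <- below_nli_values(pred, nli) - below_nli_values(obs, nli)
  mean(r)
}

#' Per-instance errors of a prediction matrix
#'
#' Computes `rmse_bl_nli` and `mean_residual_bl_nli` for every instance,
#' against the observed late motor scores.
#'
#' @param pred Prediction matrix (rows aligned with `instances`).
#' @param instances An `sci_instances` table.
#' @return data.frame with columns `patient_id`, `early_dai`, `ais`, `nli`,
#'   `rmse_bl_nli`, `mean_residual_bl_nli`.
#' @export
instance_errors <- function(pred, instances) {
  stopifnot(nrow(pred) == nrow(instances))
  obs <- target_matrix(instances)
  colnames(pred) <- motor_coords()
  out <- data.frame(patient_id = instances$patient_id,
                    early_dai = instances$early_dai,
                    ais = instances$ais, nli = instances$nli,
                    rmse_bl_nli = NA_real_, mean_residual_bl_nli = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pred))) {
    co <- myotomes_below_nli(instances$nli[i])
    r <- pred[i, co] - obs[i, co]
    out$rmse_bl_nli[i] <- sqrt(mean(r^2))
    out$mean_residual_bl_nli[i] <- mean(r)
  }
  out
}

pct <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, names = FALSE))

#' Summarize benchmark errors
#'
#' Median and empirical 2.5th/97.5th percentiles (linear interpolation
#' between order statistics) of the below-NLI RMSE and of the mean residual,
#' overall and per AIS stratum.
#'
#' @param errors data.frame from [instance_errors()].
#' @return data.frame with columns `stratum`, `n`, `rmse_median`,
#'   `rmse_p2.5`, `rmse_p97.5`, `residual_median`. Empty strata are absent.
#' @export
summarize_errors <- function(errors) {
  stopifnot(nrow(errors) > 0)
  one <- function(e, label) {
    data.frame(stratum = label, n = nrow(e),
               rmse_median = stats::median(e$rmse_bl_nli),
               rmse_p2.5 = pct(e$rmse_bl_nli, 0.025),
               rmse_p97.5 = pct(e$rmse_bl_nli, 0.975),
               residual_median = stats::median(e$mean_residual_bl_nli),
               stringsAsFactors = FALSE)
  }
  parts <- list(one(errors, "all"))
  for (g in intersect(c("A", "B", "C", "D"), unique(errors$ais))) {
    parts[[length(parts) + 1L]] <- one(errors[errors$ais == g, , drop = FALSE],
                                       paste0("AIS ", g))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Error-versus-assessment-time profile
#'
#' Daily median of the below-NLI RMSE over the day of the initial
#' assessment, smoothed with a centered 7-day rolling mean. Days without
#' data are excluded from the median step; the rolling mean at a day uses
#' whatever daily medians exist within +/- 3 days (minimum one).
#'
#' @param errors data.frame from [instance_errors()].
#' @param window Rolling window width in days (odd, default 7).
#' @return data.frame with columns `day`, `daily_median`, `rolling_mean`.
#' @export
time_profile <- function(errors, window = 7L) {
  stopifnot(window %% 2L == 1L)
  agg <- stats::aggregate(rmse_bl_nli ~ early_dai, data = errors, FUN = stats::median)
  agg <- agg[order(agg$early_dai), ]
  half <- (window - 1L) %/% 2L
  roll <- vapply(agg$early_dai, function(d) {
    mean(agg$rmse_bl_nli[abs(agg$early_dai - d) <= half])
  }, numeric(1))
  data.frame(day = agg$early_dai, daily_median = agg$rmse_bl_nli,
             rolling_mean = roll)
}

#' Permutation feature importance for one endpoint coordinate
#'
#' Importance of every encoded feature for the prediction of one motor
#' coordinate, measured by the increase in mean squared error when that
#' feature column is permuted across the probe instances (averaged over
#' `n_perm` permutations). The attribution backend is recorded in the
#' result; a model that ignores a feature scores (close to) zero.
#'
#' @param model An `sci_recovery_model`.
#' @param instances Probe `sci_instances`.
#' @param endpoint Motor coordinate name, e.g. `"L3_left"`.
#' @param n_perm Permutations per feature (default 3).
#' @param seed Integer seed.
#' @return data.frame `feature`, `score`, `rank` (1 = most important), with
#'   attribute `backend = "permutation"`.
#' @export
feature_importance <- function(model, instances, endpoint, n_perm = 3L,
                               seed = 1L) {
  stopifnot(endpoint %in% motor_coords())
  X <- encode_instances(instances)
  obs <- target_matrix(instances)[, endpoint]
  base_pred <- predict(model, instances)[, endpoint]
  base_mse <- mean((base_pred - obs)^2)
  feats <- colnames(X)
  inst_cols <- function(f) {
    # map encoded feature back to the instance-table column it came from
    if (grepl("^(ms|lt|pp)_", f)) paste0(sub("^(ms|lt|pp)_", "\\1_early_", f))
    else switch(f, sex_female = "sex", ais_A = "ais", ais_B = "ais",
                ais_C = "ais", ais_D = "ais", f)
  }
  scores <- with_seed(seed, vapply(feats, function(f) {
    col <- inst_cols(f)
    if (!col %in% names(instances)) return(0)
    d <- 0
    for (r in seq_len(n_perm)) {
      pert <- instances
      pert[[col]] <- sample(pert[[col]])
      mse <- mean((predict(model, pert)[, endpoint] - obs)^2)
      d <- d + (mse - base_mse)
    }
    d / n_perm
  }, numeric(1)))
  # one-hot AIS columns are permuted jointly via the ais column; collapse
  out <- data.frame(feature = feats, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$score, ties.method = "first")
  attr(out, "backend") <- "permutation"
  attr(out, "endpoint") <- endpoint
  out
}

#' Aggregate importances by distance from the endpoint myotome
#'
#' Groups the sequence features of an importance table into cells of
#' (signed segment distance to the endpoint level, same/opposite side,
#' modality), with the mean rank per cell; scalar covariates are reported
#' separately with `distance = NA`.
#'
#' @param imp Importance table from [feature_importance()].
#' @return data.frame `distance`, `laterality`, `modality`, `mean_rank`,
#'   `n_features`.
#' @export
aggregate_by_distance <- function(imp) {
  endpoint <- attr(imp, "endpoint")
  stopifnot(!is.null(endpoint))
  ep_level <- coord_level(endpoint)
  ep_side <- coord_side(endpoint)
  is_seq <- grepl("^(ms|lt|pp)_", imp$feature)
  seqs <- imp[is_seq, , drop = FALSE]
  coord <- sub("^(ms|lt|pp)_", "", seqs$feature)
  cell <- data.frame(
    distance = segment_distance(ep_level, coord_level(coord)),
    laterality = ifelse(coord_side(coord) == ep_side, "ipsilateral",
                        "contralateral"),
    modality = toupper(sub("_.*", "", seqs$feature)),
    rank = seqs$rank)
  agg <- stats::aggregate(rank ~ distance + laterality + modality, data = cell,
                          FUN = mean)
  names(agg)[names(agg) == "rank"] <- "mean_rank"
  counts <- stats::aggregate(rank ~ distance + laterality + modality,
                             data = cell, FUN = length)
  agg$n_features <- counts$rank
  scal <- imp[!is_seq, , drop = FALSE]
  if (nrow(scal)) {
    agg <- rbind(agg, data.frame(distance = NA, laterality = "scalar",
                                 modality = scal$feature,
                                 mean_rank = scal$rank, n_features = 1L))
  }
  rownames(agg) <- NULL
  agg
}
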