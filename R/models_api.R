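# Recovery prediction model API.
#
# Six benchmark families map an acute instance to the full 20-coordinate
# recovery-phase motor score sequence:
#   linear_regularized     ridge regression per coordinate (glmnet, inner CV)
#   random_forest          one forest per coordinate (ranger)
#   gradient_boosted_trees one booster per coordinate (xgboost)
#   conv_sequence          1-D convolutions along the rostro-caudal axis
#   seq2seq_attention      attention encoder-decoder over the myotome sequence
#   graph_sequence         message passing on the myotome chain graph
# plus reference predictors used to validate the simulation machinery:
#   baseline               carry-forward of the early scores (no-recovery null)
#   oracle                 returns the observed late scores (perfect predictor)
#   noisy_oracle           observed late scores plus Gaussian noise

MODEL_FAMILIES <- c("linear_regularized", "random_forest",
                    "gradient_boosted_trees", "conv_sequence",
                    "seq2seq_attention", "graph_sequence",
                    "baseline", "oracle", "noisy_oracle")

#' Specify a recovery prediction model
#'
#' @param family One of `linear_regularized`, `random_forest`,
#'   `gradient_boosted_trees`, `conv_sequence`, `seq2seq_attention`,
#'   `graph_sequence`, or the reference predictors `baseline`, `oracle`,
#'   `noisy_oracle`.
#' @param hyperparameters Named list of family-specific overrides (e.g.
#'   `epochs`, `hidden`, `num_trees`, `nrounds`, `sd` for `noisy_oracle`).
#' @param seed Integer seed recorded in the spec; all training randomness
#'   derives from it.
#' @return An `sci_model_spec`.
#' @export
model_spec <- function(family, hyperparameters = list(), seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "sci_model_spec")
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

clip05 <- function(x) pmin(pmax(x, 0), 5)

pid_hash <- function(id) {
  v <- utf8ToInt(as.character(id))
  as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 1e8)
}

as_pred_matrix <- function(x, n) {
  matrix(x, nrow = n)
}

# Canonical training order: fitting is invariant to the row order of the
# training table because every family sees the same sorted view.
canonical_order <- function(instances) {
  instances[order(instances$patient_id, instances$early_dai, instances$late_dai), ,
            drop = FALSE]
}

#' Fit a recovery prediction model
#'
#' Trains the family given by `spec` on an instance table. Training is
#' seed-reproducible and invariant to the row order of `train` (the table is
#' sorted canonically first). Refuses degenerate training sets with a single
#' patient.
#'
#' @param spec An `sci_model_spec`.
#' @param train An `sci_instances` table.
#' @return An `sci_recovery_model` with a [predict()] method returning the
#'   20-coordinate motor prediction matrix, clipped to \[0, 5\].
#' @export
fit_recovery_model <- function(spec, train) {
  stopifnot(inherits(spec, "sci_model_spec"), inherits(train, "sci_instances"))
  if (nrow(train) == 0) stop("empty training set")
  if (length(unique(train$patient_id)) < 2 &&
      !spec$family %in% c("baseline", "oracle", "noisy_oracle")) {
    stop("degenerate training set: need instances from at least 2 patients")
  }
  train <- canonical_order(train)
  fit <- switch(spec$family,
    baseline = list(),
    oracle = list(),
    noisy_oracle = list(sd = hp(spec, "sd", 0.5)),
    linear_regularized = with_seed(spec$seed, fit_ridge(spec, train)),
    random_forest = with_seed(spec$seed, fit_forest(spec, train)),
    gradient_boosted_trees = with_seed(spec$seed, fit_xgb(spec, train)),
    conv_sequence = with_seed(spec$seed, fit_nn(spec, train, "conv")),
    seq2seq_attention = with_seed(spec$seed, fit_nn(spec, train, "attention")),
    graph_sequence = with_seed(spec$seed, fit_nn(spec, train, "graph")))
  structure(list(spec = spec, fit = fit,
                 manifest = list(schema = ENCODING_SCHEMA,
                                 n_instances = nrow(train),
                                 n_patients = length(unique(train$patient_id)),
                                 patients = sort(unique(train$patient_id)))),
            class = "sci_recovery_model")
}

#' @export
print.sci_recovery_model <- function(x, ...) {
  cat(sprintf("<recovery model: %s, trained on %d instances (%d patients)>\n",
              x$spec$family, x$manifest$n_instances, x$manifest$n_patients))
  invisible(x)
}

#' Predict recovery-phase motor scores
#'
#' @param object An `sci_recovery_model`.
#' @param newdata An `sci_instances` table.
#' @param ... Unused.
#' @return Numeric matrix, one row per instance, 20 columns in
#'   [motor_coords()] order, values clipped to \[0, 5\].
#' @export
predict.sci_recovery_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "sci_instances"))
  fam <- object$spec$family
  if (fam %in% c("baseline", "oracle", "noisy_oracle")) {
    pred <- switch(fam,
      baseline = {
        m <- as.matrix(newdata[, ms_early_cols(), drop = FALSE])
        colnames(m) <- motor_coords()
        m
      },
      oracle = target_matrix(newdata),
      noisy_oracle = {
        # noise is a deterministic function of (seed, patient): the same
        # patient always receives the same counterfactual perturbation
        m <- target_matrix(newdata)
        noise <- with_seed(object$spec$seed, t(vapply(
          newdata$patient_id,
          function(id) {
            set.seed((object$spec$seed + pid_hash(id)) %% .Machine$integer.max)
            stats::rnorm(ncol(m), 0, object$fit$sd)
          }, numeric(ncol(m)))))
        m + noise
      })
    return(clip05(pred))
  }
  X <- encode_instances(newdata)
  if (!identical(attr(X, "schema"), object$manifest$schema)) {
    stop("encoding schema mismatch: model trained with ", object$manifest$schema)
  }
  pred <- switch(fam,
    linear_regularized = predict_ridge(object$fit, X),
    random_forest = predict_forest(object$fit, X),
    gradient_boosted_trees = predict_xgb(object$fit, X),
    conv_sequence = ,
    seq2seq_attention = ,
    graph_sequence = predict_nn(object$fit, X))
  dimnames(pred) <- list(NULL, motor_coords())
  clip05(pred)
}

# ---- linear: ridge per coordinate, penalty by inner 5-fold CV ------------

ridge_lambda_grid <- function() 10^seq(3, -3, length.out = 13)

fit_ridge <- function(spec, train) {
  X <- encode_instances(train)
  Y <- target_matrix(train)
  # patient-level inner folds, independent of row order
  pid <- train$patient_id
  upid <- sort(unique(pid))
  foldid <- if (length(upid) >= 5L) {
    (match(pid, upid) - 1L) %% 5L + 1L
  } else {
    (seq_along(pid) - 1L) %% 3L + 1L  # tiny sets: instance-level folds
  }
  coefs <- matrix(0, ncol(X) + 1L, ncol(Y),
                  dimnames = list(c("(Intercept)", colnames(X)), colnames(Y)))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    if (stats::sd(y) < 1e-12) {
      coefs[1L, j] <- y[1L]
      next
    }
    cv <- glmnet::cv.glmnet(X, y, alpha = 0, lambda = ridge_lambda_grid(),
                            foldid = foldid, standardize = TRUE)
    coefs[, j] <- as.numeric(stats::coef(cv, s = "lambda.min"))
  }
  list(coefs = coefs)
}

predict_ridge <- function(fit, X) {
  cbind(1, X) %*% fit$coefs
}

# ---- trees ---------------------------------------------------------------

fit_forest <- function(spec, train) {
  X <- encode_instances(train)
  Y <- target_matrix(train)
  ntree <- hp(spec, "num_trees", 150L)
  models <- lapply(seq_len(ncol(Y)), function(j) {
    d <- data.frame(X, y = Y[, j], check.names = FALSE)
    ranger::ranger(y ~ ., data = d, num.trees = ntree,
                   seed = spec$seed + j, num.threads = 1L,
                   respect.unordered.factors = "order")
  })
  list(models = models)
}

predict_forest <- function(fit, X) {
  d <- data.frame(X, check.names = FALSE)
  as_pred_matrix(vapply(fit$models,
                        function(m) stats::predict(m, data = d, num.threads = 1L)$predictions,
                        numeric(nrow(X))), nrow(X))
}

fit_xgb <- function(spec, train) {
  X <- encode_instances(train)
  Y <- target_matrix(train)
  nrounds <- hp(spec, "nrounds", 80L)
  models <- lapply(seq_len(ncol(Y)), function(j) {
    xgboost::xgboost(x = X, y = Y[, j], nrounds = nrounds,
                     learning_rate = hp(spec, "eta", 0.1),
                     max_depth = hp(spec, "max_depth", 4L),
                     nthreads = 1L, seed = spec$seed + j, verbosity = 0)
  })
  list(models = models)
}

predict_xgb <- function(fit, X) {
  as_pred_matrix(vapply(fit$models, function(m) stats::predict(m, newdata = X),
                        numeric(nrow(X))), nrow(X))
}

#' Persist / restore a fitted model
#'
#' Saves a fitted model as a directory: `spec.yaml` (family,
#' hyperparameters, seed), `manifest.yaml` (encoding schema, training
#' counts) and `params.rds` (learned state). The loader validates the
#' encoding schema version.
#'
#' @param model An `sci_recovery_model`.
#' @param dir Directory to create/use.
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(family = model$spec$family,
                        hyperparameters = model$spec$hyperparameters,
                        seed = model$spec$seed),
                   file.path(dir, "spec.yaml"))
  yaml::write_yaml(model$manifest[c("schema", "n_instances", "n_patients")],
                   file.path(dir, "manifest.yaml"))
  saveRDS(list(fit = model$fit, patients = model$manifest$patients),
          file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  spec_raw <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (!identical(manifest$schema, ENCODING_SCHEMA)) {
    stop("model encoding schema ", manifest$schema,
         " does not match this package (", ENCODING_SCHEMA, ")")
  }
  blob <- readRDS(file.path(dir, "params.rds"))
  manifest$patients <- blob$patients
  structure(list(spec = model_spec(spec_raw$family,
                                   hyperparameters = spec_raw$hyperparameters %||% list(),
                                   seed = spec_raw$seed),
                 fit = blob$fit, manifest = manifest),
            class = "sci_recovery_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction with input-perturbation uncertainty
#'
#' Propagates ISNCSCI assessment uncertainty through a fitted model: each
#' motor (and sensory) score of the early assessment is jittered by +/- 1
#' with probability `perturb_prob`, re-clipped to its range, and the model
#' re-applied; the per-coordinate 2.5th/97.5th percentiles over the
#' replicates (including the unperturbed prediction) form the band.
#'
#' @param model An `sci_recovery_model`.
#' @param instances An `sci_instances` table.
#' @param n_reps Number of perturbation replicates (>= 2).
#' @param perturb_prob Per-score jitter probability (default 0.1).
#' @param seed Integer seed.
#' @return List with matrices `point`, `lower`, `upper` (instances x 20).
#' @export
perturb_predict <- function(model, instances, n_reps = 30L,
                            perturb_prob = 0.1, seed = 1L) {
  stopifnot(n_reps >= 2)
  point <- predict(model, instances)
  coords <- motor_coords()
  ms_cols <- paste0("ms_early_", coords)
  lt_cols <- paste0("lt_early_", sensory_coords())
  pp_cols <- paste0("pp_early_", sensory_coords())
  jitter_block <- function(df, cols, hi) {
    m <- as.matrix(df[, cols, drop = FALSE])
    flip <- matrix(stats::runif(length(m)) < perturb_prob, nrow(m))
    step <- matrix(sample(c(-1, 1), length(m), replace = TRUE), nrow(m))
    df[, cols] <- pmin(pmax(m + flip * step, 0), hi)
    df
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      pert <- jitter_block(instances, ms_cols, 5)
      pert <- jitter_block(pert, lt_cols, 2)
      pert <- jitter_block(pert, pp_cols, 2)
      predict(model, pert)
    })
  })
  all_preds <- c(reps, list(point))
  arr <- array(unlist(all_preds), dim = c(nrow(point), ncol(point), length(all_preds)))
  lower <- apply(arr, c(1, 2), stats::quantile, probs = 0.025, names = FALSE)
  upper <- apply(arr, c(1, 2), stats::quantile, probs = 0.975, names = FALSE)
  # interpolated percentiles of few replicates can fall inside the point
  # prediction; the band contract is that it always contains the point
  lower <- pmin(lower, point)
  upper <- pmax(upper, point)
  dimnames(lower) <- dimnames(upper) <- dimnames(point)
  list(point = point, lower = lower, upper = upper)
}
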