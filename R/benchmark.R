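# Cross-validated model benchmark.

#' Patient-level cross-validation folds
#'
#' Assigns every instance to one of `k` folds such that all instances of a
#' patient share a fold (no patient straddles train and test).
#'
#' @param patient_ids Character vector, one entry per instance.
#' @param k Number of folds.
#' @param seed Integer seed for the patient shuffle.
#' @return Integer fold id per instance.
#' @export
cv_folds <- function(patient_ids, k = 5L, seed = 1L) {
  upid <- sort(unique(patient_ids))
  perm <- with_seed(seed, sample(upid))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  as.integer(fold_of[patient_ids])
}

#' Cross-validated recovery benchmark
#'
#' Trains each model family with k-fold cross-validation split by patient
#' and collects held-out per-instance below-NLI errors.
#'
#' @param instances An `sci_instances` table.
#' @param specs List of `sci_model_spec` (or character vector of families).
#' @param k Folds (default 5).
#' @param seed Integer seed; fans out to fold assignment and every fit.
#' @return List with `errors` (per-instance data.frame incl. `model` and
#'   `fold`) and `summary` (per-model [summarize_errors()] with `model`).
#' @export
benchmark_models <- function(instances, specs, k = 5L, seed = 1L) {
  if (is.character(specs)) specs <- lapply(specs, model_spec, seed = seed)
  folds <- cv_folds(instances$patient_id, k = k, seed = seed)
  all_err <- list()
  for (spec in specs) {
    for (f in sort(unique(folds))) {
      train <- instances[folds != f, , drop = FALSE]
      test <- instances[folds == f, , drop = FALSE]
      if (nrow(test) == 0) next
      model <- fit_recovery_model(spec, train)
      err <- instance_errors(predict(model, test), test)
      err$model <- spec$family
      err$fold <- f
      all_err[[length(all_err) + 1L]] <- err
    }
  }
  errors <- do.call(rbind, all_err)
  summaries <- lapply(split(errors, errors$model), function(e) {
    s <- summarize_errors(e)
    s$model <- e$model[1]
    s
  })
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(errors = errors, summary = summary)
}
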