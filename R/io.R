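# Cohort file formats and run configuration.
#
# Wide CSV (canonical on disk): one row per (patient_id, dai) with columns
#   patient_id, dai, age, sex, motor_<level>_<side> (20),
#   lt_<level>_<side> (56), pp_<level>_<side> (56), vac, dap, ais, nli.
# Long CSV (accepted for interoperability): patient_id, dai, variable,
# value, with demographics as variables (age, sex) and the same variable
# names otherwise.

wide_columns <- function() {
  c("patient_id", "dai", "age", "sex",
    paste0("motor_", motor_coords()),
    paste0("lt_", sensory_coords()),
    paste0("pp_", sensory_coords()),
    "vac", "dap", "ais", "nli")
}

assessment_to_row <- function(rec, a) {
  c(list(patient_id = rec$patient_id, dai = a$dai, age = rec$age_at_injury,
         sex = rec$sex),
    as.list(stats::setNames(a$motor, paste0("motor_", names(a$motor)))),
    as.list(stats::setNames(a$light_touch, paste0("lt_", names(a$light_touch)))),
    as.list(stats::setNames(a$pinprick, paste0("pp_", names(a$pinprick)))),
    list(vac = as.integer(a$vac), dap = as.integer(a$dap), ais = a$ais,
         nli = a$nli))
}

#' Write a cohort to CSV
#'
#' @param x A list of `sci_patient` records or an `sci_cohort`.
#' @param path Output file.
#' @param schema `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, schema = c("wide", "long")) {
  schema <- match.arg(schema)
  if (inherits(x, "sci_cohort")) x <- x$records
  rows <- list()
  for (rec in x) {
    for (a in rec$assessments) {
      rows[[length(rows) + 1L]] <- assessment_to_row(rec, a)
    }
  }
  cols <- wide_columns()
  df <- as.data.frame(
    lapply(stats::setNames(cols, cols),
           function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (schema == "long") {
    keep <- setdiff(cols, c("patient_id", "dai"))
    long <- do.call(rbind, lapply(keep, function(v) {
      data.frame(patient_id = df$patient_id, dai = df$dai, variable = v,
                 value = as.character(df[[v]]), stringsAsFactors = FALSE)
    }))
    long <- long[order(long$patient_id, long$dai, long$variable), ]
    utils::write.csv(long, path, row.names = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

sniff_schema <- function(df) {
  if (all(c("variable", "value") %in% names(df))) "long" else "wide"
}

#' Read a cohort from CSV
#'
#' Accepts the wide or the long schema (sniffed from the header unless
#' declared). Every row is validated: motor scores must be integers in 0-5,
#' sensory in 0-2; malformed scores and duplicate (patient, dai) rows raise
#' errors naming the row.
#'
#' @param path CSV file.
#' @param schema `"auto"` (default), `"wide"` or `"long"`.
#' @return List of `sci_patient` records.
#' @export
read_cohort <- function(path, schema = c("auto", "wide", "long")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (schema == "auto") schema <- sniff_schema(df)
  if (schema == "long") {
    key <- paste(df$patient_id, df$dai)
    wide <- list()
    for (k in unique(key)) {
      sub <- df[key == k, ]
      row <- stats::setNames(as.list(sub$value), sub$variable)
      row$patient_id <- sub$patient_id[1]
      row$dai <- sub$dai[1]
      wide[[length(wide) + 1L]] <- row
    }
    cols <- wide_columns()
    df <- as.data.frame(
      lapply(stats::setNames(cols, cols),
             function(cn) unlist(lapply(wide, `[[`, cn), use.names = FALSE)),
      stringsAsFactors = FALSE, check.names = FALSE)
    num_cols <- setdiff(cols, c("patient_id", "sex", "ais", "nli"))
    for (cn in num_cols) df[[cn]] <- as.numeric(df[[cn]])
  }
  if (anyDuplicated(df[, c("patient_id", "dai")])) {
    d <- which(duplicated(df[, c("patient_id", "dai")]))[1]
    stop("duplicate (patient_id, dai) at row ", d)
  }
  motor_cols <- paste0("motor_", motor_coords())
  sens_cols <- c(paste0("lt_", sensory_coords()), paste0("pp_", sensory_coords()))
  for (i in seq_len(nrow(df))) {
    m <- as.numeric(df[i, motor_cols])
    if (anyNA(m) || any(m < 0 | m > 5)) {
      stop("malformed motor score at row ", i, " (patient ", df$patient_id[i], ")")
    }
    s <- as.numeric(df[i, sens_cols])
    if (anyNA(s) || any(s < 0 | s > 2)) {
      stop("malformed sensory score at row ", i, " (patient ", df$patient_id[i], ")")
    }
  }
  records <- lapply(split(df, df$patient_id), function(sub) {
    sub <- sub[order(sub$dai), ]
    assessments <- lapply(seq_len(nrow(sub)), function(i) {
      new_assessment(sub$patient_id[i], sub$dai[i],
                     motor = stats::setNames(as.numeric(sub[i, motor_cols]),
                                             motor_coords()),
                     light_touch = stats::setNames(
                       as.numeric(sub[i, paste0("lt_", sensory_coords())]),
                       sensory_coords()),
                     pinprick = stats::setNames(
                       as.numeric(sub[i, paste0("pp_", sensory_coords())]),
                       sensory_coords()),
                     vac = sub$vac[i] > 0, dap = sub$dap[i] > 0,
                     ais = sub$ais[i], nli = sub$nli[i])
    })
    new_patient_record(sub$patient_id[1], sub$age[1], sub$sex[1], assessments)
  })
  unname(records[order(names(records))])
}

#' Serialize / deserialize a cohort generator configuration
#'
#' Round-trippable key/value (YAML) representation of an
#' `sci_cohort_config`.
#'
#' @param config An `sci_cohort_config`.
#' @param path Destination / source file.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.null(names(x))) x else as.list(x)
  }), path, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_config, raw[setdiff(names(raw), character(0))])
}

#' Run the full pipeline
#'
#' Executes generate -> include -> train -> evaluate -> simulate -> power on
#' a synthetic cohort and writes every summary as CSV into `out_dir`,
#' stamped with the configuration hash and seed in `manifest.yaml`.
#' Re-running with the same configuration reproduces the outputs.
#'
#' @param config Named list: `n_patients`, `seed`, `families` (character),
#'   `cv_folds`, `n_trials`, `trial_size`, `epochs` (NN override, optional),
#'   `delta`, `alpha`, `power`. Missing entries take defaults sized for a
#'   demonstration run.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(
    n_patients = 500L, seed = 1L, families = c("baseline", "linear_regularized"),
    cv_folds = 5L, n_trials = 50L, trial_size = 100L, epochs = NULL,
    delta = 5, alpha = 0.05, power = 0.8), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  write_manifest <- function() {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- if (inherits(res, "error")) {
      list(status = "failed", error = conditionMessage(res))
    } else list(status = "ok")
    write_manifest()
    if (inherits(res, "error")) stop("stage '", name, "' failed: ",
                                     conditionMessage(res))
    res
  }

  cohort <- stage("generate", {
    co <- generate_cohort(default_emsci_config(n_patients = cfg$n_patients,
                                               seed = cfg$seed))
    write_cohort(co, file.path(out_dir, "cohort.csv"))
    co
  })
  inst <- stage("include", {
    x <- benchmark_inclusion(cohort)
    utils::write.csv(data.frame(stage = c("generated", "included"),
                                n = c(length(cohort$records), nrow(x))),
                     file.path(out_dir, "inclusion_counts.csv"),
                     row.names = FALSE)
    x
  })
  bench <- stage("train_evaluate", {
    hyper <- if (is.null(cfg$epochs)) list() else list(epochs = cfg$epochs)
    specs <- lapply(cfg$families, function(f) {
      model_spec(f, hyperparameters = if (f %in% c("conv_sequence",
                                                   "seq2seq_attention",
                                                   "graph_sequence")) hyper
                 else list(), seed = cfg$seed)
    })
    b <- benchmark_models(inst, specs, k = cfg$cv_folds, seed = cfg$seed)
    utils::write.csv(b$summary, file.path(out_dir, "benchmark_summary.csv"),
                     row.names = FALSE)
    b
  })
  sim <- stage("simulate", {
    # train/simulate split by patient: the model never sees pool patients
    upid <- sort(unique(inst$patient_id))
    half <- with_seed(cfg$seed, sample(upid, length(upid) %/% 2))
    train <- inst[inst$patient_id %in% half, , drop = FALSE]
    pool <- trial_pool(cohort)
    pool <- pool[!pool$patient_id %in% half, , drop = FALSE]
    fam <- cfg$families[cfg$families != "baseline"][1]
    model <- fit_recovery_model(model_spec(fam, seed = cfg$seed), train)
    s <- repeat_trials(pool, min(cfg$trial_size, nrow(pool)), model,
                       n_trials = cfg$n_trials, base_seed = cfg$seed)
    utils::write.csv(cbind(config_hash = cfg_hash, s$replicates),
                     file.path(out_dir, "simulation_replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(config_hash = cfg_hash, s$summary),
                     file.path(out_dir, "simulation_summary.csv"),
                     row.names = FALSE)
    s
  })
  pow <- stage("power", {
    p <- design_params(cfg$delta, 10, cfg$alpha, cfg$power)
    tab <- data.frame(design = c("single_arm", "rct_per_group", "rct_total"),
                      n = c(paired_n(p), two_sample_n(p), 2L * two_sample_n(p)))
    utils::write.csv(tab, file.path(out_dir, "power_reference.csv"),
                     row.names = FALSE)
    tab
  })
  manifest$completed <- TRUE
  write_manifest()
  invisible(list(cohort = cohort, instances = inst, benchmark = bench,
                 simulation = sim, power = pow, config = cfg,
                 config_hash = cfg_hash))
}
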