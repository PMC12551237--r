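# Feature encoding: instance table -> numeric design matrix.
#
# Sequence block: for each of the 20 key-muscle coordinates (rostro-caudal,
# left before right) the early motor score plus the aligned light-touch and
# pinprick scores at the same level/side (60 features). Scalar block: age,
# sex, assessment times, AIS one-hot, VAC, DAP, NLI index (11 features).
# Late motor scores are never encoded (no target leakage).

ENCODING_SCHEMA <- "sctsim-enc-1"

scalar_feature_names <- function() {
  c("age", "sex_female", "early_dai", "late_dai",
    paste0("ais_", c("A", "B", "C", "D")), "vac", "dap", "nli_index")
}

sequence_feature_names <- function() {
  coords <- motor_coords()
  as.vector(rbind(paste0("ms_", coords), paste0("lt_", coords),
                  paste0("pp_", coords)))
}

#' Encode instances as a design matrix
#'
#' Deterministic, schema-versioned encoding of the early assessment and
#' covariates. Column order is fixed: 60 sequence features (per key-muscle
#' coordinate: motor, light touch, pinprick), then 11 scalar covariates.
#'
#' @param instances An `sci_instances` table.
#' @return Numeric matrix with `schema` attribute; one row per instance.
#' @export
encode_instances <- function(instances) {
  stopifnot(inherits(instances, "sci_instances"), nrow(instances) > 0)
  coords <- motor_coords()
  need <- c(paste0("ms_early_", coords), paste0("lt_early_", coords),
            paste0("pp_early_", coords))
  missing <- setdiff(need, names(instances))
  if (length(missing)) {
    stop("encoding error: missing field(s) ", paste(missing[1:min(3, length(missing))],
                                                    collapse = ", "))
  }
  seq_block <- matrix(0, nrow(instances), 60,
                      dimnames = list(NULL, sequence_feature_names()))
  for (co in coords) {
    seq_block[, paste0("ms_", co)] <- instances[[paste0("ms_early_", co)]]
    seq_block[, paste0("lt_", co)] <- instances[[paste0("lt_early_", co)]]
    seq_block[, paste0("pp_", co)] <- instances[[paste0("pp_early_", co)]]
  }
  scal <- cbind(age = instances$age,
                sex_female = as.numeric(instances$sex == "female"),
                early_dai = instances$early_dai,
                late_dai = instances$late_dai,
                ais_A = as.numeric(instances$ais == "A"),
                ais_B = as.numeric(instances$ais == "B"),
                ais_C = as.numeric(instances$ais == "C"),
                ais_D = as.numeric(instances$ais == "D"),
                vac = instances$vac, dap = instances$dap,
                nli_index = instances$nli_index)
  X <- cbind(seq_block, scal)
  attr(X, "schema") <- ENCODING_SCHEMA
  X
}

# Target matrix: the 20 late motor scores, column order = motor_coords().
target_matrix <- function(instances) {
  Y <- as.matrix(instances[, ms_late_cols(), drop = FALSE])
  colnames(Y) <- motor_coords()
  Y
}
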