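#' @keywords internal
"_PACKAGE"

# The 28 ISNCSCI spinal levels in rostro-caudal order. Indexing is 0-based so
# that segment distances read directly as "number of segments caudal".
SPINAL_LEVELS <- c(
  "C2", "C3", "C4", "C5", "C6", "C7", "C8",
  paste0("T", 1:12),
  paste0("L", 1:5),
  "S1", "S2", "S3", "S4-5"
)

# The 10 key muscles (myotomes) with a motor score per side.
KEY_MUSCLES <- c("C5", "C6", "C7", "C8", "T1", "L2", "L3", "L4", "L5", "S1")
UEMS_LEVELS <- c("C5", "C6", "C7", "C8", "T1")
LEMS_LEVELS <- c("L2", "L3", "L4", "L5", "S1")
SIDES <- c("left", "right")

#' ISNCSCI spinal levels
#'
#' The 28 spinal levels of the ISNCSCI examination in rostro-caudal order,
#' with their 0-based index. The index order equals anatomical order, so
#' differences of indices are signed segment distances.
#'
#' @return A data.frame with columns `label` and `index` (0 to 27).
#' @export
#' @examples
#' head(spinal_levels())
spinal_levels <- function() {
  data.frame(label = SPINAL_LEVELS, index = seq_along(SPINAL_LEVELS) - 1L,
             stringsAsFactors = FALSE)
}

#' Index of a spinal level
#'
#' @param label Character vector of level labels (e.g. `"C5"`, `"S4-5"`).
#' @return Integer vector of 0-based rostro-caudal indices.
#' @export
level_index <- function(label) {
  idx <- match(label, SPINAL_LEVELS)
  if (anyNA(idx)) {
    stop("unknown spinal level(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Signed segment distance between two spinal levels
#'
#' Positive when `b` is caudal to `a`.
#'
#' @param a,b Level labels (vectors recycle).
#' @return Integer vector `index(b) - index(a)`.
#' @export
#' @examples
#' segment_distance("C5", "C7") #  2
#' segment_distance("T1", "C8") # -1
segment_distance <- function(a, b) {
  level_index(b) - level_index(a)
}

#' Motor coordinate names
#'
#' The 20 key-muscle coordinates `<level>_<side>` in rostro-caudal order,
#' left before right within a level. This is the canonical coordinate order
#' used by all score vectors, predictions and encodings in the package.
#'
#' @return Character vector of length 20.
#' @export
motor_coords <- function() {
  as.vector(t(outer(KEY_MUSCLES, SIDES, paste, sep = "_")))
}

sensory_coords <- function() {
  as.vector(t(outer(SPINAL_LEVELS, SIDES, paste, sep = "_")))
}

coord_level <- function(coord) sub("_(left|right)$", "", coord)
coord_side <- function(coord) sub("^.*_", "", coord)

#' Key myotomes strictly caudal to the neurological level of injury
#'
#' Returns the motor coordinates (both sides) strictly caudal to `nli`, the
#' set over which below-NLI prediction errors are computed. Moving the NLI
#' one level caudal never adds coordinates.
#'
#' @param nli Level label of the neurological level of injury; must be
#'   rostral to S1 (patients with NLI at or below S1 are excluded upstream).
#' @return Character vector of motor coordinates in rostro-caudal order.
#' @export
#' @examples
#' myotomes_below_nli("C6") # 16 coordinates, C7 .. S1
#' length(myotomes_below_nli("T6")) # 10: the lumbosacral myotomes
myotomes_below_nli <- function(nli) {
  stopifnot(length(nli) == 1L)
  i <- level_index(nli)
  if (i >= level_index("S1")) {
    stop("NLI at or below S1: patient excluded from below-NLI analysis")
  }
  keep <- level_index(KEY_MUSCLES) > i
  as.vector(t(outer(KEY_MUSCLES[keep], SIDES, paste, sep = "_")))
}

# Region of a level: cervical C2-C8, thoracic T1-T12, lumbar L1-L5, sacral.
nli_region <- function(label) {
  i <- level_index(label)
  ifelse(i <= 6L, "cervical",
         ifelse(i <= 18L, "thoracic",
                ifelse(i <= 23L, "lumbar", "sacral")))
}
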