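#' Movement conditions of the trunk-motion protocol
#'
#' The protocol comprises seven metronome-paced lumbar movement conditions:
#' three uniaxial (flexion-extension, side-bending, axial rotation) and four
#' multiaxial (flexion+rotation, rotation+side-bending, side-bending+flexion,
#' and circumduction about the cranial-caudal axis, i.e. flexion and
#' side-bending in quadrature).
#'
#' @return A data frame with one row per condition: `id`, `trial` (1-7),
#'   `label`, and logical columns `fx`, `sb`, `rt` flagging the active axes.
#' @export
#' @examples
#' movement_conditions()
movement_conditions <- function() {
  data.frame(
    id = CONDITION_IDS,
    trial = 1:7,
    label = c("Flexion", "Side-bending", "Rotation",
              "Flexion + Rotation", "Rotation + Side-bending",
              "Side-bending + Flexion",
              "Moving around cranial-caudal axis"),
    fx = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    sb = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    rt = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

CONDITION_IDS <- c("FLEXION", "SIDE_BENDING", "ROTATION",
                   "FLEXION_ROTATION", "ROTATION_SIDEBENDING",
                   "SIDEBENDING_FLEXION", "CRANIAL_CAUDAL_CIRCUMDUCTION")

AXES <- c("fx_deg", "sb_deg", "rt_deg")

#' Default per-condition movement half-amplitudes
#'
#' Half-ROM amplitudes (degrees) for each condition's active axes; a sinusoid
#' of amplitude A has range of motion 2A. Values are half of the study-protocol
#' mean ROM for the axes a condition actively drives; inactive axes are 0.
#' The circumduction condition drives flexion and side-bending with a 90 deg
#' relative phase.
#'
#' @return 7 x 3 numeric matrix, rows named by condition id, columns
#'   `fx_deg`, `sb_deg`, `rt_deg`.
#' @export
default_amplitudes <- function() {
  m <- rbind(
    FLEXION                      = c(33.82, 0,     0)     / 2,
    SIDE_BENDING                 = c(0,     12.42, 0)     / 2,
    ROTATION                     = c(0,     0,     11.22) / 2,
    FLEXION_ROTATION             = c(24.07, 0,     10.83) / 2,
    ROTATION_SIDEBENDING         = c(0,     18.01, 12.46) / 2,
    SIDEBENDING_FLEXION          = c(24.47, 17.26, 0)     / 2,
    CRANIAL_CAUDAL_CIRCUMDUCTION = c(31.19, 16.86, 0)     / 2
  )
  colnames(m) <- AXES
  m
}

# Phase offsets (degrees) per condition and axis; circumduction puts
# side-bending in quadrature with flexion so the FX-SB trace is a circle.
condition_phases <- function() {
  m <- matrix(0, nrow = 7, ncol = 3, dimnames = list(CONDITION_IDS, AXES))
  m["CRANIAL_CAUDAL_CIRCUMDUCTION", "sb_deg"] <- 90
  m
}

match_condition <- function(condition) {
  if (!(is.character(condition) && length(condition) == 1 &&
        condition %in% CONDITION_IDS)) {
    lum_error(sprintf("unknown movement condition '%s'",
                      paste(condition, collapse = ",")),
              class = "lum_condition_error")
  }
  condition
}
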