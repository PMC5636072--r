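#' Marker names of the ten-landmark trunk/pelvis set
#'
#' @format Character vector of the ten anatomical landmarks: C7, right/left
#'   acromion, the L1-level triad, right/left ASIS, L5 and the coccyx.
#' @export
MARKER_NAMES <- c("C7", "ACR_R", "ACR_L", "L1_L", "L1", "L1_R",
                  "ASIS_R", "ASIS_L", "L5", "COCC")

TRUNK_MARKERS <- c("C7", "ACR_R", "ACR_L", "L1_L", "L1", "L1_R")
PELVIS_MARKERS <- c("ASIS_R", "ASIS_L", "L5", "COCC")

#' Neutral-pose skeleton template
#'
#' Landmark positions (mm, global frame) of an upright neutral pose for the
#' ten-marker set, plus the lumbar joint center about which the trunk segment
#' rotates. Global axes: X to the subject's right, Y anterior, Z cranial.
#' The template is bilaterally symmetric and constructed so that both the
#' pelvis and trunk anatomical frames are exactly the identity in neutral
#' pose, which makes simulated angles directly comparable to recovered ones.
#'
#' @param stature_scale Multiplier applied to all positions (1 = the default
#'   ~1.67 m stature geometry).
#' @return List with `landmarks` (10 x 3 matrix, rows named), `joint_center`
#'   (length-3), `trunk_markers`, `pelvis_markers`.
#' @export
#' @examples
#' sk <- skeleton_template()
#' sk$landmarks["C7", ]
skeleton_template <- function(stature_scale = 1) {
  landmarks <- rbind(
    C7     = c(0, -90, 400),
    ACR_R  = c(190, -30, 360),
    ACR_L  = c(-190, -30, 360),
    L1_L   = c(-40, -90, 60),
    L1     = c(0, -90, 60),
    L1_R   = c(40, -90, 60),
    ASIS_R = c(120, 80, -100),
    ASIS_L = c(-120, 80, -100),
    L5     = c(0, -80, -60),
    COCC   = c(0, -85, -140)
  ) * stature_scale
  colnames(landmarks) <- c("x", "y", "z")
  sk <- list(landmarks = landmarks,
             joint_center = c(0, -85, 0) * stature_scale,
             trunk_markers = TRUNK_MARKERS,
             pelvis_markers = PELVIS_MARKERS)
  class(sk) <- "skeleton_template"
  validate_skeleton(sk)
  sk
}

validate_skeleton <- function(sk) {
  lm <- sk$landmarks
  if (!all(MARKER_NAMES %in% rownames(lm))) {
    lum_error("skeleton template must define all ten landmarks",
              class = "lum_skeleton_error")
  }
  pairs <- list(c("ACR_R", "ACR_L"), c("L1_R", "L1_L"), c("ASIS_R", "ASIS_L"))
  for (p in pairs) {
    mirrored <- lm[p[2], ] * c(-1, 1, 1)
    if (max(abs(lm[p[1], ] - mirrored)) > 1e-9) {
      lum_error(sprintf("landmarks %s/%s are not sagittally symmetric",
                        p[1], p[2]), class = "lum_skeleton_error")
    }
  }
  zj <- sk$joint_center[3]
  if (zj <= lm["L5", "z"] || zj >= lm["L1", "z"]) {
    lum_error("lumbar joint center must lie between L5 and L1 heights",
              class = "lum_skeleton_error")
  }
  invisible(sk)
}

#' Stretch-sensor mounting layout
#'
#' Geometry metadata for the four sheet sensors on the lower back: two
#' vertical sensors offset 100 mm laterally from the back midline at the L5
#' level, and two oblique sensors running at 45 degrees from the L5 level
#' toward the mid-back. All sensors have a 70 mm initial (mounted) length.
#' The layout is descriptive: the forward signal model works through the
#' configured gain matrix, not through skin geometry.
#'
#' @param initial_length_mm Mounted sensor length, mm.
#' @return Data frame with one row per channel: name, orientation, proximal
#'   and distal anchor coordinates (mm), initial length.
#' @export
sensor_layout <- function(initial_length_mm = 70) {
  if (initial_length_mm <= 0) {
    lum_error("initial sensor length must be positive",
              class = "lum_layout_error")
  }
  l5_z <- -60   # template L5 height
  y <- -95      # just proximal to the skin surface plane of the back
  obl <- initial_length_mm / sqrt(2)
  d <- data.frame(
    channel = c("dl1_mm", "dl2_mm", "dl3_mm", "dl4_mm"),
    orientation = c("vertical_right", "vertical_left",
                    "oblique_right", "oblique_left"),
    prox_x = c(100, -100, 30, -30),
    prox_y = y, prox_z = l5_z,
    dist_x = c(100, -100, 30 + obl, -30 - obl),
    dist_y = y,
    dist_z = c(l5_z + initial_length_mm, l5_z + initial_length_mm,
               l5_z + obl, l5_z + obl),
    initial_length_mm = initial_length_mm,
    stringsAsFactors = FALSE
  )
  d
}
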