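# Marker-based reference kinematics: anatomical frames for pelvis and trunk,
# relative rotation, and the Cardan X-Y-Z (flexion - lateral bending -
# rotation) decomposition.

GIMBAL_EPS <- 1e-6

vnorm <- function(v) sqrt(sum(v^2))

unit3 <- function(v, what, frame = NA) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-9) {
    msg <- sprintf("degenerate marker geometry while building %s", what)
    if (!is.na(frame)) msg <- sprintf("%s (frame %d)", msg, frame)
    lum_error(msg, class = "lum_degenerate_geometry_error", frame = frame)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

marker_row <- function(frame, name) {
  if (is.matrix(frame)) {
    if (!(name %in% rownames(frame))) {
      lum_error(sprintf("marker %s missing from frame", name),
                class = "lum_schema_error")
    }
    as.numeric(frame[name, ])
  } else {
    if (is.null(frame[[name]])) {
      lum_error(sprintf("marker %s missing from frame", name),
                class = "lum_schema_error")
    }
    as.numeric(frame[[name]])
  }
}

#' Anatomical coordinate frames from one marker frame
#'
#' `build_pelvis_frame()`: x is the unit vector from left to right ASIS; the
#' provisional y runs from the midpoint of L5 and the coccyx to the ASIS
#' midpoint; z = x cross y0, y = z cross x. `build_trunk_frame()`: x from left
#' to right acromion; provisional z from L1 up to C7; y = z0 cross x,
#' z = x cross y. Both return orthonormal matrices with the axes as columns
#' and reduce to the identity in the neutral skeleton template.
#'
#' @param frame Named 10 x 3 matrix (rows = marker names) or named list of
#'   3-vectors, mm.
#' @return 3 x 3 rotation matrix, columns = (x, y, z).
#' @export
#' @examples
#' sk <- skeleton_template()
#' build_pelvis_frame(sk$landmarks)  # identity in neutral pose
build_pelvis_frame <- function(frame) {
  asis_r <- marker_row(frame, "ASIS_R"); asis_l <- marker_row(frame, "ASIS_L")
  l5 <- marker_row(frame, "L5"); cocc <- marker_row(frame, "COCC")
  x <- unit3(asis_r - asis_l, "pelvis x axis")
  p <- (l5 + cocc) / 2
  y0 <- unit3((asis_r + asis_l) / 2 - p, "pelvis provisional y axis")
  z <- unit3(cross3(x, y0), "pelvis z axis")
  y <- cross3(z, x)
  cbind(x, y, z, deparse.level = 0)
}

#' @rdname build_pelvis_frame
#' @export
build_trunk_frame <- function(frame) {
  acr_r <- marker_row(frame, "ACR_R"); acr_l <- marker_row(frame, "ACR_L")
  c7 <- marker_row(frame, "C7"); l1 <- marker_row(frame, "L1")
  x <- unit3(acr_r - acr_l, "trunk x axis")
  z0 <- unit3(c7 - l1, "trunk provisional z axis")
  y <- unit3(cross3(z0, x), "trunk y axis")
  z <- cross3(x, y)
  cbind(x, y, z, deparse.level = 0)
}

#' Relative rotation between two frames
#'
#' @param pelvis,trunk Orthonormal 3 x 3 rotation matrices.
#' @return `t(pelvis) %*% trunk`.
#' @export
relative_rotation <- function(pelvis, trunk) {
  check_rotation(pelvis); check_rotation(trunk)
  t(pelvis) %*% trunk
}

check_rotation <- function(r, tol = 1e-6) {
  if (!is.matrix(r) || !all(dim(r) == c(3, 3)) ||
      max(abs(crossprod(r) - diag(3))) > tol) {
    lum_error("matrix is not orthonormal", class = "lum_rotation_error")
  }
  invisible(r)
}

#' Cardan X-Y-Z decomposition of a rotation matrix
#'
#' Decomposes `R = Rx(fx) %*% Ry(sb) %*% Rz(rt)`: flexion-extension about X,
#' then side-bending about Y, then axial rotation about Z. Angles are in
#' degrees; `sb = asin(R[1,3])`, `fx = atan2(-R[2,3], R[3,3])`,
#' `rt = atan2(-R[1,2], R[1,1])`.
#'
#' @param r Orthonormal 3 x 3 rotation matrix.
#' @return Named numeric vector `c(fx_deg, sb_deg, rt_deg)`.
#' @export
#' @examples
#' r <- diag(3)
#' cardan_xyz_decompose(r)  # c(0, 0, 0)
cardan_xyz_decompose <- function(r) {
  check_rotation(r)
  if (abs(r[1, 3]) > 1 - GIMBAL_EPS) {
    lum_error("side-bending angle too close to 90 degrees (gimbal lock)",
              class = "lum_gimbal_lock_error")
  }
  k <- 180 / pi
  c(fx_deg = atan2(-r[2, 3], r[3, 3]) * k,
    sb_deg = asin(r[1, 3]) * k,
    rt_deg = atan2(-r[1, 2], r[1, 1]) * k)
}

#' Reference lumbar angles from marker trajectories
#'
#' Per frame: build pelvis and trunk frames, form the relative rotation and
#' decompose it with the Cardan X-Y-Z sequence. The resulting angle series is
#' offset so that frame 0 reads (0, 0, 0) - the angular-displacement
#' convention shared with the offset sensor channels. No filtering is done
#' here; see [butterworth_lowpass()].
#'
#' @param markers Marker trajectory data frame (`time_s` +
#'   `<MARKER>_x/_y/_z`).
#' @param zero_first_frame Offset the series to zero at frame 0 (default
#'   TRUE).
#' @return An `angle_series`.
#' @export
compute_reference_angles <- function(markers, zero_first_frame = TRUE) {
  check_marker_frame(markers)
  n <- nrow(markers)
  col3 <- function(m) {
    cbind(markers[[paste0(m, "_x")]], markers[[paste0(m, "_y")]],
          markers[[paste0(m, "_z")]])
  }
  normalize_rows <- function(v, what) {
    nv <- sqrt(rowSums(v^2))
    bad <- which(!is.finite(nv) | nv < 1e-9)
    if (length(bad)) {
      lum_error(sprintf("degenerate marker geometry while building %s (frame %d)",
                        what, bad[1]),
                class = "lum_degenerate_geometry_error", frame = bad[1])
    }
    v / nv
  }
  crossr <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  # Pelvis axes
  px <- normalize_rows(col3("ASIS_R") - col3("ASIS_L"), "pelvis x axis")
  pmid <- (col3("L5") + col3("COCC")) / 2
  py0 <- normalize_rows((col3("ASIS_R") + col3("ASIS_L")) / 2 - pmid,
                        "pelvis provisional y axis")
  pz <- normalize_rows(crossr(px, py0), "pelvis z axis")
  py <- crossr(pz, px)
  # Trunk axes
  tx <- normalize_rows(col3("ACR_R") - col3("ACR_L"), "trunk x axis")
  tz0 <- normalize_rows(col3("C7") - col3("L1"), "trunk provisional z axis")
  ty <- normalize_rows(crossr(tz0, tx), "trunk y axis")
  tz <- crossr(tx, ty)
  # Needed entries of R_rel = t(P) %*% T: R_rel[i, j] = p_i . t_j
  r13 <- rowSums(px * tz); r23 <- rowSums(py * tz); r33 <- rowSums(pz * tz)
  r12 <- rowSums(px * ty); r11 <- rowSums(px * tx)
  if (any(abs(r13) > 1 - GIMBAL_EPS)) {
    lum_error(sprintf("gimbal lock near frame %d",
                      which(abs(r13) > 1 - GIMBAL_EPS)[1]),
              class = "lum_gimbal_lock_error")
  }
  k <- 180 / pi
  fx <- atan2(-r23, r33) * k
  sb <- asin(pmin(1, pmax(-1, r13))) * k
  rt <- atan2(-r12, r11) * k
  if (zero_first_frame && n > 0) {
    fx <- fx - fx[1]; sb <- sb - sb[1]; rt <- rt - rt[1]
  }
  new_angle_series(markers$time_s, fx, sb, rt)
}

check_marker_frame <- function(markers) {
  need <- c("time_s", as.vector(t(outer(MARKER_NAMES, c("_x", "_y", "_z"),
                                        paste0))))
  missing <- setdiff(need, names(markers))
  if (length(missing)) {
    lum_error(sprintf("marker data missing columns: %s",
                      paste(missing, collapse = ", ")),
              class = "lum_schema_error", columns = missing)
  }
  if (anyNA(markers[need])) {
    bad <- which(rowSums(is.na(markers[need])) > 0)[1]
    lum_error(sprintf("NaN/NA marker data at row %d", bad),
              class = "lum_schema_error", row = bad)
  }
  invisible(markers)
}
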