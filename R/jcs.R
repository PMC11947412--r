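#' Rigid pose of the tibia relative to the femur
#'
#' A rigid pose holds the rotation that maps tibial-frame vectors into the
#' femoral frame and the position of the tibial origin expressed in the
#' femoral frame. At the neutral pose both implant frames coincide, with
#' x pointing anteriorly, y proximally (distal to proximal) and z laterally
#' for a right knee (medial to lateral).
#'
#' @param rotation 3x3 proper orthogonal matrix (tibial -> femoral vectors).
#' @param translation numeric(3), tibial origin in the femoral frame, mm.
#' @param side `"right"` or `"left"`. The side flag flips the reported signs
#'   of adduction, internal rotation and medial-lateral translation so that
#'   clinical directions keep their meaning on either limb.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                       side = c("right", "left")) {
  side <- match.arg(side)
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (length(translation) != 3L) stop("translation must have length 3")
  if (!is_proper_rotation(rotation)) {
    stop("invalid pose: rotation is not proper orthogonal within 1e-10")
  }
  structure(list(rotation = rotation, translation = translation, side = side),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid_pose (", x$side, " knee)\n", sep = "")
  cat("  translation [mm]:", format(x$translation, digits = 6), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Grood-Suntay joint coordinates
#'
#' The six motion components of the tibiofemoral joint coordinate system:
#' rotations about the femoral body-fixed medial-lateral axis (flexion), the
#' floating axis (adduction) and the tibial body-fixed long axis (internal
#' rotation), and translations along those three axes. Angles in degrees,
#' translations in mm.
#'
#' @param flexion_deg,adduction_deg,internal_rot_deg rotations, degrees.
#' @param ml_mm,ap_mm,is_mm translations along the medial-lateral, floating
#'   (anterior-posterior) and long (inferior-superior) axes, mm.
#' @return An object of class `jcs_coords` (named numeric of length 6).
#' @export
jcs_coordinates <- function(flexion_deg = 0, adduction_deg = 0,
                            internal_rot_deg = 0, ml_mm = 0, ap_mm = 0,
                            is_mm = 0) {
  if (abs(adduction_deg) >= 90) {
    stop("adduction_deg must lie strictly inside (-90, 90) degrees")
  }
  structure(c(flexion_deg = flexion_deg, adduction_deg = adduction_deg,
              internal_rot_deg = internal_rot_deg, ml_mm = ml_mm,
              ap_mm = ap_mm, is_mm = is_mm),
            class = "jcs_coords")
}

#' @export
print.jcs_coords <- function(x, ...) {
  cat("jcs_coords: flexion", format(x[["flexion_deg"]], digits = 6),
      "deg, adduction", format(x[["adduction_deg"]], digits = 6),
      "deg, int.rot", format(x[["internal_rot_deg"]], digits = 6), "deg\n")
  cat("            ml", format(x[["ml_mm"]], digits = 6),
      "mm, ap", format(x[["ap_mm"]], digits = 6),
      "mm, is", format(x[["is_mm"]], digits = 6), "mm\n")
  invisible(x)
}

#' Conjugate loads in the joint coordinate system
#'
#' Forces along the three joint-coordinate axes and moments about them.
#' Sign convention (fixed, documented): positive `ap_force_N` pushes the
#' tibia anteriorly; the inferior-superior axis points proximally, so a
#' compressive joint load appears as a negative `is_force_N`.
#'
#' @param ml_force_N,ap_force_N,is_force_N forces, N.
#' @param flexion_moment_Nm,adduction_moment_Nm,internal_rot_moment_Nm
#'   moments, N m.
#' @return An object of class `jcs_load` (named numeric of length 6).
#' @export
jcs_load <- function(ml_force_N = 0, ap_force_N = 0, is_force_N = 0,
                     flexion_moment_Nm = 0, adduction_moment_Nm = 0,
                     internal_rot_moment_Nm = 0) {
  structure(c(ml_force_N = ml_force_N, ap_force_N = ap_force_N,
              is_force_N = is_force_N, flexion_moment_Nm = flexion_moment_Nm,
              adduction_moment_Nm = adduction_moment_Nm,
              internal_rot_moment_Nm = internal_rot_moment_Nm),
            class = "jcs_load")
}

# The three joint axes at a pose, expressed in the femoral frame:
# e1 femoral medial->lateral (body-fixed z), e3 tibial distal->proximal
# (rotated tibial y), e2 = e3 x e1 normalised (floating axis).
jcs_axes <- function(pose) {
  e1 <- c(0, 0, 1)
  e3 <- pose$rotation[, 2]
  e2 <- cross3(e3, e1)
  n2 <- norm3(e2)
  list(e1 = e1, e2 = e2 / n2, e3 = e3, sin_beta = e3[3])
}

gimbal_check <- function(sin_beta, tol_deg = 1e-6) {
  beta_deg <- asin(min(1, max(-1, sin_beta))) * RAD2DEG
  if (90 - abs(beta_deg) <= tol_deg) {
    stop(sprintf(paste0("joint coordinate singularity: adduction angle ",
                        "%.8f deg is within %g deg of +/-90 (flexion axis ",
                        "parallel to the tibial long axis)"),
         beta_deg, tol_deg))
  }
  beta_deg
}

#' Convert a rigid pose to Grood-Suntay coordinates
#'
#' Decomposes the pose into the six joint-coordinate components. The
#' convention is singular when the femoral flexion axis becomes parallel to
#' the tibial long axis (adduction of +/-90 degrees); poses within 1e-6
#' degrees of the singularity are rejected with an explicit error rather
#' than clamped.
#'
#' @param pose a [rigid_pose()].
#' @return A [jcs_coordinates()] object. Composing with [pose_from_jcs()]
#'   recovers the pose to better than 1e-9.
#' @export
jcs_from_pose <- function(pose) {
  stopifnot(inherits(pose, "rigid_pose"))
  R <- pose$rotation
  if (!is_proper_rotation(R)) {
    stop("invalid pose: rotation is not proper orthogonal within 1e-10")
  }
  beta_deg <- gimbal_check(R[3, 2])
  beta <- beta_deg * DEG2RAD
  alpha <- atan2(-R[1, 2], R[2, 2])
  gamma <- atan2(-R[3, 1], R[3, 3])

  ax <- jcs_axes(pose)
  t <- pose$translation
  ap <- sum(t * ax$e2)
  # e1 and e3 are non-orthogonal (e1.e3 = sin beta): solve the 2x2 oblique
  # system t.e1 = ml + is*s, t.e3 = ml*s + is
  s <- ax$sin_beta
  d <- 1 - s^2
  p1 <- sum(t * ax$e1)
  p3 <- sum(t * ax$e3)
  ml <- (p1 - s * p3) / d
  is <- (p3 - s * p1) / d

  sgn <- if (pose$side == "left") -1 else 1
  jcs_coordinates(flexion_deg = alpha * RAD2DEG,
                  adduction_deg = sgn * beta_deg,
                  internal_rot_deg = sgn * gamma * RAD2DEG,
                  ml_mm = sgn * ml, ap_mm = ap, is_mm = is)
}

#' Build a rigid pose from Grood-Suntay coordinates
#'
#' Inverse of [jcs_from_pose()]: the rotation is assembled as flexion about
#' the femoral medial-lateral axis, adduction about the floating axis and
#' internal rotation about the tibial long axis; the translation is placed
#' along the (oblique) joint axes.
#'
#' @param coords a [jcs_coordinates()] object or named numeric with the same
#'   six elements.
#' @param side `"right"` (default) or `"left"`.
#' @return A [rigid_pose()].
#' @export
pose_from_jcs <- function(coords, side = c("right", "left")) {
  side <- match.arg(side)
  q <- as.numeric(coords[c("flexion_deg", "adduction_deg", "internal_rot_deg",
                           "ml_mm", "ap_mm", "is_mm")])
  if (anyNA(q)) stop("coords must carry the six named JCS components")
  if (abs(q[2]) >= 90) {
    stop("adduction_deg out of the open interval (-90, 90) degrees")
  }
  sgn <- if (side == "left") -1 else 1
  alpha <- q[1] * DEG2RAD
  beta <- sgn * q[2] * DEG2RAD
  gamma <- sgn * q[3] * DEG2RAD
  R <- rot_z(alpha) %*% rot_x(beta) %*% rot_y(gamma)
  pose <- rigid_pose(R, c(0, 0, 0), side = side)
  ax <- jcs_axes(pose)
  t <- sgn * q[4] * ax$e1 + q[5] * ax$e2 + q[6] * ax$e3
  rigid_pose(R, t, side = side)
}

#' Express an applied wrench as Grood-Suntay loads
#'
#' Projects a wrench acting at the tibial origin onto the three joint axes:
#' force components along e1/e2/e3 and moment components about the same axes
#' (the convention a hybrid-control joint simulator displays). The strict
#' generalized-force conjugate of the joint coordinates (which adds the
#' translation-carrying coupling terms) is available via
#' `method = "conjugate"` and satisfies the virtual-work identity exactly.
#'
#' @param w a [wrench()] expressed in femoral-frame axes with its moment
#'   taken about the tibial origin (origin equal to `pose$translation`, or a
#'   tibial-frame wrench about the tibial origin, which is rotated first).
#' @param pose the current [rigid_pose()].
#' @param method `"projection"` (default) or `"conjugate"`.
#' @return A [jcs_load()].
#' @export
jcs_load_from_wrench <- function(w, pose, method = c("projection", "conjugate")) {
  method <- match.arg(method)
  stopifnot(inherits(w, "wrench"), inherits(pose, "rigid_pose"))
  F <- w$force_N
  M <- w$moment_Nm
  if (identical(w$frame_id, "tibial")) {
    if (norm3(w$origin_mm) > 1e-9) {
      stop("frame mismatch: tibial-frame wrench must be taken about the tibial origin; re-express it first")
    }
    F <- as.numeric(pose$rotation %*% F)
    M <- as.numeric(pose$rotation %*% M)
  } else if (identical(w$frame_id, "femoral")) {
    if (norm3(w$origin_mm - pose$translation) > 1e-9) {
      stop("frame mismatch: wrench origin is not the tibial origin; re-express it first")
    }
  } else {
    stop(sprintf("frame mismatch: wrench frame '%s' is neither 'femoral' nor 'tibial'", w$frame_id))
  }
  ax <- jcs_axes(pose)
  gimbal_check(ax$sin_beta)
  sgn <- if (pose$side == "left") -1 else 1
  if (method == "projection") {
    return(jcs_load(ml_force_N = sgn * sum(F * ax$e1),
                    ap_force_N = sum(F * ax$e2),
                    is_force_N = sum(F * ax$e3),
                    flexion_moment_Nm = sum(M * ax$e1),
                    adduction_moment_Nm = sgn * sum(M * ax$e2),
                    internal_rot_moment_Nm = sgn * sum(M * ax$e3)))
  }
  # conjugate generalized forces: t = ml e1 + ap e2 + is e3 with e2, e3
  # functions of the angles; translation coupling terms are in N mm and are
  # converted to N m so that angular components stay conjugate to radians.
  q <- jcs_from_pose(pose)
  ml <- sgn * q[["ml_mm"]]; ap <- q[["ap_mm"]]; is <- q[["is_mm"]]
  de2_da <- cross3(ax$e1, ax$e2)
  de3_da <- cross3(ax$e1, ax$e3)
  de3_db <- cross3(ax$e2, ax$e3)
  q_flex <- sum(M * ax$e1) + sum(F * (ap * de2_da + is * de3_da)) / 1000
  q_add <- sum(M * ax$e2) + sum(F * (is * de3_db)) / 1000
  q_ir <- sum(M * ax$e3)
  jcs_load(ml_force_N = sgn * sum(F * ax$e1),
           ap_force_N = sum(F * ax$e2),
           is_force_N = sum(F * ax$e3),
           flexion_moment_Nm = q_flex,
           adduction_moment_Nm = sgn * q_add,
           internal_rot_moment_Nm = sgn * q_ir)
}
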