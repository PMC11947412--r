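# Shared fixtures, built in code.

# random non-singular pose (adduction within +/- limit_deg)
random_pose <- function(limit_deg = 60) {
  pose_from_jcs(jcs_coordinates(
    flexion_deg = stats::runif(1, -170, 170),
    adduction_deg = stats::runif(1, -limit_deg, limit_deg),
    internal_rot_deg = stats::runif(1, -170, 170),
    ml_mm = stats::runif(1, -20, 20),
    ap_mm = stats::runif(1, -20, 20),
    is_mm = stats::runif(1, -20, 20)))
}

random_wrench <- function(frame_id = "femoral", origin_mm = c(0, 0, 0)) {
  wrench(force_N = stats::runif(3, -500, 500),
         moment_Nm = stats::runif(3, -20, 20),
         frame_id = frame_id, origin_mm = origin_mm)
}

# mirror-symmetric apparatus: two vertical strand pairs at +/- z, all
# attachments in the x = 0 plane so the anterior-posterior equilibrium under
# pure compression is the symmetric one
symmetric_apparatus <- function(k = 2000, er = 0.02) {
  ligament_apparatus(list(
    ligament_strand("med_vert", "medial", c(0, 10, -20), c(0, -40, -20), k, er),
    ligament_strand("lat_vert", "lateral", c(0, 10, 20), c(0, -40, 20), k, er),
    ligament_strand("med_cap", "capsular", c(0, 5, -30), c(0, -35, -30), k / 2, er),
    ligament_strand("lat_cap", "capsular", c(0, 5, 30), c(0, -35, 30), k / 2, er)))
}

# single-condyle plane surface: sphere radius 25 centred on the axis, plane
# at -23.5, so the axial gap at neutral is 0.5 mm
plane_surface <- function(radius = 25, gap = 0.5) {
  contact_surface(radius, matrix(c(0, 2, 0), 1), "plane",
                  plane_y_mm = 2 - radius - gap, condyles = "medial")
}

# an apparatus whose single strand is always slack (ligaments effectively off)
slack_apparatus <- function() {
  set_reference_pose(
    ligament_apparatus(list(
      ligament_strand("slack", "capsular", c(0, 60, 0), c(0, -60, 0),
                      100, -0.5))),
    rigid_pose())
}

# adjoint-matrix oracle for wrench re-expression: rows act on c(F, M)
adjoint_oracle <- function(w, reg) {
  Qt <- t(reg$rotation)
  A <- rbind(cbind(Qt, matrix(0, 3, 3)),
             cbind(Qt %*% kneetwin:::skew3(reg$origin_shift_mm) / 1000, Qt))
  M0 <- w$moment_Nm + kneetwin:::cross3(w$origin_mm, w$force_N) / 1000
  as.numeric(A %*% c(w$force_N, M0))
}

# homogeneous-matrix oracle for pose re-registration
homogeneous_oracle <- function(p, reg_f, reg_t) {
  Hp <- rbind(cbind(p$rotation, p$translation), c(0, 0, 0, 1))
  Tf <- rbind(cbind(t(reg_f$rotation),
                    t(reg_f$rotation) %*% reg_f$origin_shift_mm),
              c(0, 0, 0, 1))
  Tt <- rbind(cbind(t(reg_t$rotation),
                    t(reg_t$rotation) %*% reg_t$origin_shift_mm),
              c(0, 0, 0, 1))
  Tf %*% Hp %*% solve(Tt)
}

# finite-difference virtual-work oracle: work done by a wrench through the
# twist induced by perturbing each joint coordinate (N m; translations mm,
# angles deg at the interface)
fd_generalized_forces <- function(w, pose, h = 1e-6) {
  q0 <- as.numeric(jcs_from_pose(pose))
  names(q0) <- c("flexion_deg", "adduction_deg", "internal_rot_deg",
                 "ml_mm", "ap_mm", "is_mm")
  out <- numeric(6)
  for (j in 1:6) {
    qp <- q0; qp[j] <- qp[j] + h
    qm <- q0; qm[j] <- qm[j] - h
    pp <- pose_from_jcs(qp, side = pose$side)
    pm <- pose_from_jcs(qm, side = pose$side)
    dt <- (pp$translation - pm$translation) / (2 * h)
    dR <- (pp$rotation - pm$rotation) / (2 * h)
    W <- dR %*% t(pose$rotation)
    om <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
    out[j] <- sum(w$force_N * dt) / 1000 + sum(w$moment_Nm * om)
  }
  out
}

# the analytic conjugate loads on the same per-degree / per-mm scale as the
# finite-difference oracle
conjugate_on_fd_scale <- function(g) {
  c(c(g[["flexion_moment_Nm"]], g[["adduction_moment_Nm"]],
      g[["internal_rot_moment_Nm"]]) * pi / 180,
    c(g[["ml_force_N"]], g[["ap_force_N"]], g[["is_force_N"]]) / 1000)
}
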