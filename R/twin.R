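#' Machine compliance of the joint simulator frame
#'
#' A joint simulator deforms elastically under axial load without sensing
#' the deformation; the axial compliance (mm per N) quantifies that sag.
#'
#' @param axial_mm_per_N compliance c >= 0 (0 = rigid machine).
#' @return An object of class `machine_compliance`.
#' @export
machine_compliance <- function(axial_mm_per_N = 0) {
  if (!is.numeric(axial_mm_per_N) || axial_mm_per_N < 0) {
    stop("axial compliance must be >= 0")
  }
  structure(list(axial_mm_per_N = axial_mm_per_N),
            class = "machine_compliance")
}

# combined contact + ligament load in JCS components at a pose
combined_jcs_load <- function(pose, app, surface, params) {
  cw <- contact_wrench(pose, surface, params)
  lw <- apparatus_wrench(app, pose)
  total <- wrench(force_N = cw$wrench$force_N + lw$force_N,
                  moment_Nm = cw$wrench$moment_Nm + lw$moment_Nm,
                  frame_id = "femoral", origin_mm = pose$translation)
  list(total = jcs_load_from_wrench(total, pose),
       contact = jcs_load_from_wrench(cw$wrench, pose),
       ligament = jcs_load_from_wrench(lw, pose),
       penetration_mm = cw$penetration_mm,
       normal_force_N = cw$normal_force_N)
}

free_components <- c("adduction_deg", "ml_mm", "ap_mm", "is_mm")
target_components <- c("adduction_moment_Nm", "ml_force_N", "ap_force_N",
                       "is_force_N")

solve_residual <- function(x, fe_deg, ei_deg, targets, app, surface, params,
                           side) {
  pose <- pose_from_jcs(jcs_coordinates(flexion_deg = fe_deg,
                                        adduction_deg = x[1],
                                        internal_rot_deg = ei_deg,
                                        ml_mm = x[2], ap_mm = x[3],
                                        is_mm = x[4]),
                        side = side)
  g <- combined_jcs_load(pose, app, surface, params)
  r <- as.numeric(g$total[target_components]) - targets
  list(r = r, pose = pose, load = g)
}

#' Solve one hybrid-control equilibrium step
#'
#' Flexion and external-internal rotation are clamped to their position
#' targets; the four force/moment-controlled components (abduction-adduction,
#' medial-lateral, anterior-posterior, inferior-superior) are found by
#' driving the combined contact-plus-ligament load to the target load with a
#' damped (Levenberg-style) Newton iteration on a central-difference
#' Jacobian. Non-convergence is reported, not raised, so a running load case
#' can continue.
#'
#' @param position_targets named numeric with `fe_deg` and `ei_deg`.
#' @param load_targets a [jcs_load()]; the `adduction_moment_Nm`,
#'   `ml_force_N`, `ap_force_N` and `is_force_N` components are matched.
#' @param app a referenced [ligament_apparatus()].
#' @param surface a [contact_surface()].
#' @param params a [contact_params()].
#' @param guess optional [jcs_coordinates()] warm start.
#' @param side knee side.
#' @param tol_force_N,tol_moment_Nm convergence tolerances (0.5 N, 0.05 N m).
#' @param max_iter maximum Newton iterations (50).
#' @return A list with `coords` ([jcs_coordinates()]), `converged`,
#'   `residual_force_N` and `residual_moment_Nm` (recomputed from the
#'   returned pose), `contact`, `ligament` and `total` [jcs_load()]s,
#'   `penetration_mm`, `normal_force_N` and `iterations`.
#' @export
solve_equilibrium_step <- function(position_targets, load_targets, app,
                                   surface, params, guess = NULL,
                                   side = "right", tol_force_N = 0.5,
                                   tol_moment_Nm = 0.05, max_iter = 50) {
  fe <- as.numeric(position_targets[["fe_deg"]])
  ei <- as.numeric(position_targets[["ei_deg"]])
  targets <- as.numeric(load_targets[target_components])
  scale_r <- c(tol_moment_Nm, tol_force_N, tol_force_N, tol_force_N)
  # the iteration aims well below the reporting tolerance so the solved pose
  # is a reproducible function of the targets (not of the warm start)
  inner_scale <- 1e-4 * scale_r
  fstep <- c(1e-5, 1e-5, 1e-5, 1e-5)  # deg / mm central-difference steps

  lm_solve <- function(x, budget) {
    ev <- solve_residual(x, fe, ei, targets, app, surface, params, side)
    lambda <- 1e-3
    it <- 0L
    while (it < budget) {
      if (all(abs(ev$r) < inner_scale)) break
      it <- it + 1L
      J <- matrix(0, 4, 4)
      for (j in 1:4) {
        xp <- x; xp[j] <- xp[j] + fstep[j]
        xm <- x; xm[j] <- xm[j] - fstep[j]
        J[, j] <- (solve_residual(xp, fe, ei, targets, app, surface, params, side)$r -
                   solve_residual(xm, fe, ei, targets, app, surface, params, side)$r) /
          (2 * fstep[j])
      }
      JtJ <- crossprod(J)
      g <- crossprod(J, ev$r)
      improved <- FALSE
      # damping floor relative to the dominant curvature so that unconstrained
      # directions (e.g. no in-plane contact stiffness) stay regularised
      dfloor <- pmax(diag(JtJ), 1e-8 * max(diag(JtJ), 1))
      for (k in 1:12) {
        A <- JtJ + lambda * diag(dfloor)
        dx <- tryCatch(-solve(A, g), error = function(e) NULL)
        if (is.null(dx)) { lambda <- lambda * 10; next }
        # backtracking guards against overshooting the piecewise-smooth
        # kinks of penalty contact (liftoff) and the ligament law
        for (alpha in c(1, 0.5, 0.25, 0.125)) {
          xn <- x + alpha * as.numeric(dx)
          xn[1] <- min(89, max(-89, xn[1]))  # keep clear of the JCS singularity
          evn <- solve_residual(xn, fe, ei, targets, app, surface, params, side)
          if (sum((evn$r / scale_r)^2) < sum((ev$r / scale_r)^2)) {
            x <- xn
            ev <- evn
            lambda <- max(lambda / 3, 1e-10)
            improved <- TRUE
            break
          }
        }
        if (improved) break
        lambda <- lambda * 10
      }
      if (!improved) break  # stalled (kink or local minimum)
    }
    list(x = x, ev = ev, iterations = it)
  }

  # warm start first; on a stall, deterministic restarts from neutral seats
  starts <- list(if (is.null(guess)) c(0, 0, 0, 1) else
                   as.numeric(guess[free_components]),
                 c(0, 0, 0, 1), c(0, 0, 0, 2), c(0, 0, -1, 1.5))
  best <- NULL
  it <- 0L
  for (s in starts) {
    if (it >= max_iter) break
    # cap each attempt so a crawling warm start cannot starve the restarts
    trial <- lm_solve(s, min(max_iter - it, 20L))
    it <- it + trial$iterations
    if (is.null(best) ||
        sum((trial$ev$r / scale_r)^2) < sum((best$ev$r / scale_r)^2)) {
      best <- trial
    }
    if (all(abs(best$ev$r) < inner_scale)) break
  }
  x <- best$x
  # independent residual recomputation from the returned pose
  final <- solve_residual(x, fe, ei, targets, app, surface, params, side)
  rf <- max(abs(final$r[2:4]))
  rm <- abs(final$r[1])
  list(coords = jcs_coordinates(flexion_deg = fe, adduction_deg = x[1],
                                internal_rot_deg = ei, ml_mm = x[2],
                                ap_mm = x[3], is_mm = x[4]),
       converged = rf < tol_force_N && rm < tol_moment_Nm,
       residual_force_N = rf, residual_moment_Nm = rm,
       contact = final$load$contact, ligament = final$load$ligament,
       total = final$load$total,
       penetration_mm = final$load$penetration_mm,
       normal_force_N = final$load$normal_force_N,
       iterations = it)
}

#' Run a periodised load case on the quasi-static twin
#'
#' Solves the hybrid-control equilibrium at every sample of the track, warm
#' starting each step from the previous solution, and repeats the cycle
#' until the quasi-static trajectory is cycle-periodic (for a memoryless
#' system the second cycle already reproduces the first up to the warm-start
#' transient of the very first step). The last cycle is reported.
#'
#' @param track a periodised [load_case_track()].
#' @param app a referenced [ligament_apparatus()].
#' @param surface a [contact_surface()].
#' @param params a [contact_params()].
#' @param cycles number of cycles to run (>= 1, default 2).
#' @param side knee side.
#' @param variant label stored with the result (e.g. `"reference"`,
#'   `"resect:PCL"`).
#' @param ... passed to [solve_equilibrium_step()].
#' @return An object of class `simulation_result`: `steps` (one row per time
#'   step of the last cycle), `adl`, `variant`, `frequency_hz`,
#'   `cycle_change` (max absolute pose-coordinate change between the last
#'   two cycles), `failed` (more than 10% non-converged steps) and
#'   `n_unconverged`.
#' @export
run_load_case <- function(track, app, surface, params, cycles = 2,
                          side = "right", variant = "reference", ...) {
  stopifnot(inherits(track, "load_case_track"))
  if (!track$periodised) {
    stop("track is not periodised; run prepare_load_case()/periodise() first")
  }
  if (is.null(app$reference_pose)) {
    stop("apparatus is not referenced; call set_reference_pose() first")
  }
  cycles <- max(1L, as.integer(cycles))
  n <- length(track$time_s)
  ch <- track$channels
  guess <- NULL
  prev_cycle <- NULL
  cycle_change <- NA_real_
  steps <- NULL
  for (cy in seq_len(cycles)) {
    rows <- vector("list", n)
    coords_mat <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      st <- solve_equilibrium_step(
        position_targets = c(fe_deg = ch$fe_deg[i], ei_deg = ch$ei_deg[i]),
        load_targets = jcs_load(ml_force_N = ch$ml_N[i],
                                ap_force_N = ch$ap_N[i],
                                is_force_N = ch$is_N[i],
                                adduction_moment_Nm = ch$abad_Nm[i]),
        app = app, surface = surface, params = params, guess = guess,
        side = side, ...)
      guess <- st$coords
      coords_mat[i, ] <- as.numeric(st$coords)
      rows[[i]] <- data.frame(
        time_s = track$time_s[i],
        fe_deg = st$coords[["flexion_deg"]],
        adduction_deg = st$coords[["adduction_deg"]],
        ei_deg = st$coords[["internal_rot_deg"]],
        ml_mm = st$coords[["ml_mm"]],
        ap_mm = st$coords[["ap_mm"]],
        is_mm = st$coords[["is_mm"]],
        contact_ml_N = st$contact[["ml_force_N"]],
        contact_ap_N = st$contact[["ap_force_N"]],
        contact_is_N = st$contact[["is_force_N"]],
        contact_abad_Nm = st$contact[["adduction_moment_Nm"]],
        ligament_ml_N = st$ligament[["ml_force_N"]],
        ligament_ap_N = st$ligament[["ap_force_N"]],
        ligament_is_N = st$ligament[["is_force_N"]],
        medial_force_N = st$normal_force_N[["medial"]] %||% NA_real_,
        lateral_force_N = st$normal_force_N[["lateral"]] %||% NA_real_,
        residual_force_N = st$residual_force_N,
        residual_moment_Nm = st$residual_moment_Nm,
        iterations = st$iterations,
        converged = st$converged)
    }
    steps <- do.call(rbind, rows)
    if (!is.null(prev_cycle)) {
      cycle_change <- max(abs(coords_mat - prev_cycle))
    }
    prev_cycle <- coords_mat
  }
  n_unconv <- sum(!steps$converged)
  structure(list(steps = steps, adl = track$adl, variant = variant,
                 frequency_hz = track$frequency_hz,
                 cycle_change = cycle_change,
                 n_unconverged = n_unconv,
                 failed = n_unconv > 0.1 * n),
            class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", x$adl, "| variant", x$variant, "|",
      nrow(x$steps), "steps |", x$n_unconverged, "unconverged",
      if (x$failed) "| FAILED" else "", "\n")
  cat("  max residuals:", format(max(x$steps$residual_force_N), digits = 3),
      "N,", format(max(x$steps$residual_moment_Nm), digits = 3), "N m;",
      "cycle change:", format(x$cycle_change, digits = 3), "\n")
  invisible(x)
}

#' Time-weighted mean axial load of one cycle
#'
#' Trapezoidal mean of the inferior-superior force channel over the track's
#' time grid; negative values are compressive.
#'
#' @param track a [load_case_track()].
#' @return Mean axial load, N.
#' @export
mean_axial_load <- function(track) {
  stopifnot(inherits(track, "load_case_track"))
  y <- track$channels$is_N
  if (is.null(y)) stop("track has no inferior-superior force channel")
  t <- track$time_s
  n <- length(t)
  area <- sum((y[-1] + y[-n]) / 2 * diff(t))
  area / (t[n] - t[1])
}

#' Reference the apparatus under the mean compressive load
#'
#' A joint simulator that sags elastically under load misreads the reference
#' pose, and hence every strand's reference length, when referencing happens
#' unloaded. The established compensation references the joint under the
#' load case's mean compression: here the nominal reference pose is shifted
#' axially by `compliance * mean axial load` (a compressive, negative mean
#' moves the tibia distally by the sag) before strand lengths are recorded.
#' With zero compliance this is exactly [set_reference_pose()] at the
#' nominal pose.
#'
#' @param app a [ligament_apparatus()].
#' @param track the [load_case_track()] whose mean axial load sets the sag.
#' @param compliance a [machine_compliance()].
#' @param nominal_pose the nominal reference pose (default: neutral).
#' @return The referenced apparatus.
#' @export
apply_compliance_compensation <- function(app, track, compliance,
                                          nominal_pose = rigid_pose()) {
  stopifnot(inherits(app, "ligament_apparatus"),
            inherits(compliance, "machine_compliance"),
            inherits(nominal_pose, "rigid_pose"))
  f_mean <- mean_axial_load(track)
  sag <- compliance$axial_mm_per_N * f_mean
  ax <- jcs_axes(nominal_pose)
  shifted <- rigid_pose(nominal_pose$rotation,
                        nominal_pose$translation + sag * ax$e3,
                        side = nominal_pose$side)
  set_reference_pose(app, shifted)
}

#' Flexion-binned comparison of two simulation results
#'
#' Splits the samples of each run into flexion (non-negative flexion rate)
#' and extension phases, bins them by flexion angle, and reports per-bin
#' mean differences (b minus a) of the anterior-posterior translation, the
#' abduction-adduction angle and the transmitted (contact) axial force —
#' the standard way soft-tissue variants are compared on a joint simulator.
#'
#' @param result_a,result_b [run_load_case()] results from the same track.
#' @param bin_deg flexion bin width, degrees.
#' @return A data frame with one row per (phase, bin): bin edges and centre,
#'   sample counts, and `d_ap_mm`, `d_adduction_deg`, `d_is_force_N`.
#' @export
flexion_binned_comparison <- function(result_a, result_b, bin_deg = 10) {
  stopifnot(inherits(result_a, "simulation_result"),
            inherits(result_b, "simulation_result"))
  if (!identical(result_a$adl, result_b$adl) ||
      nrow(result_a$steps) != nrow(result_b$steps) ||
      max(abs(result_a$steps$time_s - result_b$steps$time_s)) > 1e-12) {
    stop("results are from different tracks and cannot be compared")
  }
  fe <- result_a$steps$fe_deg
  n <- length(fe)
  rate <- c(fe[2] - fe[1], (fe[3:n] - fe[1:(n - 2)]) / 2, fe[n] - fe[n - 1])
  phase <- ifelse(rate >= 0, "flexion", "extension")
  lo <- floor(min(fe) / bin_deg) * bin_deg
  hi <- ceiling(max(fe) / bin_deg) * bin_deg
  edges <- seq(lo, hi, by = bin_deg)
  if (length(edges) < 2) edges <- c(lo, lo + bin_deg)
  bin <- cut(fe, edges, include.lowest = TRUE, right = FALSE)
  out <- list()
  for (ph in c("flexion", "extension")) {
    for (bi in levels(bin)) {
      sel <- phase == ph & bin == bi
      if (!any(sel)) next
      k <- which(levels(bin) == bi)
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, bin_lo_deg = edges[k], bin_hi_deg = edges[k + 1],
        bin_mid_deg = (edges[k] + edges[k + 1]) / 2,
        n = sum(sel),
        d_ap_mm = mean(result_b$steps$ap_mm[sel]) -
          mean(result_a$steps$ap_mm[sel]),
        d_adduction_deg = mean(result_b$steps$adduction_deg[sel]) -
          mean(result_a$steps$adduction_deg[sel]),
        d_is_force_N = mean(result_b$steps$contact_is_N[sel]) -
          mean(result_a$steps$contact_is_N[sel]))
    }
  }
  do.call(rbind, out)
}
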