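#' Wrench: a force/moment pair with frame and origin tags
#'
#' @param force_N numeric(3) force, N.
#' @param moment_Nm numeric(3) moment, N m, taken about `origin_mm`.
#' @param frame_id label of the frame the components are expressed in.
#' @param origin_mm numeric(3), the point (in that frame, mm) the moment is
#'   taken about.
#' @return An object of class `wrench`.
#' @export
wrench <- function(force_N = c(0, 0, 0), moment_Nm = c(0, 0, 0),
                   frame_id = "tibial", origin_mm = c(0, 0, 0)) {
  force_N <- unname(as.numeric(force_N))
  moment_Nm <- unname(as.numeric(moment_Nm))
  origin_mm <- unname(as.numeric(origin_mm))
  stopifnot(length(force_N) == 3L, length(moment_Nm) == 3L,
            length(origin_mm) == 3L)
  structure(list(force_N = force_N, moment_Nm = moment_Nm,
                 frame_id = frame_id, origin_mm = origin_mm),
            class = "wrench")
}

#' @export
print.wrench <- function(x, ...) {
  cat("wrench in frame '", x$frame_id, "' about [",
      paste(format(x$origin_mm, digits = 4), collapse = ", "), "] mm\n",
      sep = "")
  cat("  F [N]  :", format(x$force_N, digits = 6), "\n")
  cat("  M [N m]:", format(x$moment_Nm, digits = 6), "\n")
  invisible(x)
}

#' Rigid registration between two implant coordinate systems
#'
#' Describes how a source implant frame is re-registered into a target
#' implant frame: `rotation` is the attitude of the target frame expressed
#' in the source frame (coordinates transform through its transpose) and
#' `origin_shift_mm` is the position of the source origin measured from the
#' target origin, expressed in source-frame axes.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param origin_shift_mm numeric(3), mm.
#' @param source_frame,target_frame frame labels.
#' @return An object of class `frame_registration`.
#' @export
frame_registration <- function(rotation = diag(3),
                               origin_shift_mm = c(0, 0, 0),
                               source_frame = "source",
                               target_frame = "target") {
  rotation <- unname(as.matrix(rotation))
  origin_shift_mm <- unname(as.numeric(origin_shift_mm))
  if (!is_proper_rotation(rotation)) {
    stop("registration rotation is not proper orthogonal within 1e-10")
  }
  stopifnot(length(origin_shift_mm) == 3L)
  structure(list(rotation = rotation, origin_shift_mm = origin_shift_mm,
                 source_frame = source_frame, target_frame = target_frame),
            class = "frame_registration")
}

#' Default registration from the instrumented to the cruciate-retaining design
#'
#' The instrumented ultra-congruent implant of the source dataset was
#' implanted with a steeper posterior tibial slope than the cruciate-retaining
#' design the load cases are transferred to. Matching the functional surfaces
#' under an equal-slope assumption amounts to a 6.5 degree tilt about the
#' medial-lateral axis plus sub-millimetre shifts of the coordinate origin.
#'
#' @param slope_correction_deg tilt about the medial-lateral axis, degrees.
#' @param origin_shift_mm origin shift (norm at most 1 mm by default), mm.
#' @return A [frame_registration()] from frame `"INNEX"` to `"PFC_SIGMA"`.
#' @export
default_registration <- function(slope_correction_deg = 6.5,
                                 origin_shift_mm = c(0.5, -0.7, 0.3)) {
  frame_registration(
    rotation = rotation_about_axis(c(0, 0, 1), slope_correction_deg),
    origin_shift_mm = origin_shift_mm,
    source_frame = "INNEX", target_frame = "PFC_SIGMA")
}

#' @export
print.frame_registration <- function(x, ...) {
  aa <- axis_angle(x$rotation)
  cat("frame_registration ", x$source_frame, " -> ", x$target_frame, "\n",
      sep = "")
  cat("  rotation:", format(aa$angle_deg, digits = 6), "deg about [",
      paste(format(aa$axis, digits = 4), collapse = ", "), "]\n")
  cat("  origin shift [mm]:", format(x$origin_shift_mm, digits = 4), "\n")
  invisible(x)
}

#' Re-express a wrench in another implant frame
#'
#' Rotates force and moment into the target frame after moving the moment
#' reference point to the target origin (adding the origin-shift cross
#' product). The force norm and the invariant force--moment product are
#' preserved.
#'
#' @param w a [wrench()] whose `frame_id` matches the registration's source.
#' @param reg a [frame_registration()].
#' @return A [wrench()] in the target frame about the target origin.
#' @export
register_wrench <- function(w, reg) {
  stopifnot(inherits(w, "wrench"), inherits(reg, "frame_registration"))
  if (!identical(w$frame_id, reg$source_frame)) {
    stop(sprintf("frame mismatch: wrench is in '%s' but registration starts from '%s'",
                 w$frame_id, reg$source_frame))
  }
  # moment about the source origin first (origin_mm is relative to source
  # origin), then about the target origin: lever arm = source origin as seen
  # from the target origin, in mm -> N m via /1000
  M0 <- w$moment_Nm + cross3(w$origin_mm, w$force_N) / 1000
  Mt <- M0 + cross3(reg$origin_shift_mm, w$force_N) / 1000
  Q <- reg$rotation
  wrench(force_N = as.numeric(t(Q) %*% w$force_N),
         moment_Nm = as.numeric(t(Q) %*% Mt),
         frame_id = reg$target_frame, origin_mm = c(0, 0, 0))
}

# inverse of a registration (target -> source)
invert_registration <- function(reg) {
  Q <- reg$rotation
  frame_registration(rotation = t(Q),
                     origin_shift_mm = as.numeric(-t(Q) %*% reg$origin_shift_mm),
                     source_frame = reg$target_frame,
                     target_frame = reg$source_frame)
}

#' Re-register a relative pose under new component frames
#'
#' Applies a registration to the femoral component frame and one to the
#' tibial component frame and returns the tibia-relative-to-femur pose
#' expressed in the new frames. With equal registrations on both sides this
#' models re-registering the whole joint (the matched-surface assumption);
#' identity registrations leave the pose unchanged.
#'
#' @param p a [rigid_pose()].
#' @param reg_femoral,reg_tibial [frame_registration()] objects; `reg_tibial`
#'   defaults to `reg_femoral`.
#' @return A [rigid_pose()].
#' @export
register_pose <- function(p, reg_femoral, reg_tibial = reg_femoral) {
  stopifnot(inherits(p, "rigid_pose"),
            inherits(reg_femoral, "frame_registration"),
            inherits(reg_tibial, "frame_registration"))
  Qf <- reg_femoral$rotation
  Qt <- reg_tibial$rotation
  R_new <- t(Qf) %*% p$rotation %*% Qt
  # new tibial origin in old tibial coords is -origin_shift (shift is the old
  # origin seen from the new one); push through old pose, then into the new
  # femoral frame whose origin sits at -shift_f in old femoral coords
  o_t_new <- p$translation + as.numeric(p$rotation %*% (-reg_tibial$origin_shift_mm))
  t_new <- as.numeric(t(Qf) %*% (o_t_new + reg_femoral$origin_shift_mm))
  rigid_pose(R_new, t_new, side = p$side)
}

#' Body-weight scaling configuration
#'
#' Telemetric load datasets are commonly normalised to a reference body
#' weight; the AVER75 convention scales load magnitudes to a 75 kg subject.
#'
#' @param reference_body_weight_kg body weight the source loads refer to.
#' @param target_body_weight_kg body weight to scale to (default 75).
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(reference_body_weight_kg,
                           target_body_weight_kg = 75) {
  if (!is.numeric(reference_body_weight_kg) || reference_body_weight_kg <= 0 ||
      !is.numeric(target_body_weight_kg) || target_body_weight_kg <= 0) {
    stop("body weights must be positive")
  }
  structure(list(reference_body_weight_kg = reference_body_weight_kg,
                 target_body_weight_kg = target_body_weight_kg),
            class = "scaling_config")
}

adl_levels <- c("level_walking", "downhill_walking", "stairs_down",
                "squat", "sit_to_stand")

track_channel_names <- c("fe_deg", "ei_deg", "ml_N", "ap_N", "is_N", "abad_Nm")

track_roles <- c(fe_deg = "position", ei_deg = "position",
                 ml_N = "force", ap_N = "force", is_N = "force",
                 abad_Nm = "force")

#' One activity-of-daily-living load-case cycle
#'
#' A load-case track carries one cycle of the six simulator target channels
#' on a uniform time grid: flexion-extension and external-internal rotation
#' are position-controlled; the anterior-posterior, medial-lateral and
#' inferior-superior forces and the abduction-adduction moment are
#' force/moment-controlled. A negative `is_N` is a compressive joint load.
#'
#' @param adl one of `"level_walking"`, `"downhill_walking"`,
#'   `"stairs_down"`, `"squat"`, `"sit_to_stand"`.
#' @param time_s strictly increasing uniform time grid, s.
#' @param channels data frame with columns `fe_deg`, `ei_deg`, `ml_N`,
#'   `ap_N`, `is_N`, `abad_Nm`.
#' @param frequency_hz cycle rate, Hz.
#' @param frame frame label the channels are expressed in.
#' @param periodised whether the track has been harmonised for cyclic control.
#' @param extra optional data frame of supplementary channels (e.g. the
#'   flexion and axial-rotation moments produced by re-registration).
#' @return An object of class `load_case_track`.
#' @export
load_case_track <- function(adl, time_s, channels, frequency_hz,
                            frame = "INNEX", periodised = FALSE,
                            extra = NULL) {
  adl <- match.arg(adl, adl_levels)
  time_s <- as.numeric(time_s)
  n <- length(time_s)
  if (n < 2L) stop("track needs at least two samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("time grid must be uniform within 1e-9 s")
  if (!is.numeric(frequency_hz) || frequency_hz <= 0) {
    stop("frequency_hz must be positive")
  }
  channels <- as.data.frame(channels)
  missing <- setdiff(track_channel_names, names(channels))
  if (length(missing)) {
    stop("missing track channel(s): ", paste(missing, collapse = ", "))
  }
  channels <- channels[track_channel_names]
  if (nrow(channels) != n) stop("channels and time grid lengths differ")
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != n) stop("extra channels and time grid lengths differ")
  }
  structure(list(adl = adl, time_s = time_s, channels = channels,
                 frequency_hz = frequency_hz, frame = frame,
                 roles = track_roles, periodised = isTRUE(periodised),
                 extra = extra),
            class = "load_case_track")
}

#' @export
print.load_case_track <- function(x, ...) {
  cat("load_case_track:", x$adl, "|", length(x$time_s), "samples |",
      format(x$frequency_hz, digits = 4), "Hz | frame", x$frame,
      if (x$periodised) "| periodised" else "| raw", "\n")
  cat("  peak flexion:", format(max(x$channels$fe_deg), digits = 4),
      "deg; peak compression:", format(min(x$channels$is_N), digits = 6),
      "N\n")
  invisible(x)
}

#' Scale the load channels of a track to a target body weight
#'
#' Multiplies the force/moment-controlled channels by the ratio of target to
#' reference body weight; position-controlled (kinematic) channels and the
#' cycle frequency are left untouched. Moments scale by the same ratio as
#' forces because the lever arms are unchanged.
#'
#' @param track a [load_case_track()].
#' @param cfg a [scaling_config()].
#' @return The scaled [load_case_track()].
#' @export
scale_loads <- function(track, cfg) {
  stopifnot(inherits(track, "load_case_track"),
            inherits(cfg, "scaling_config"))
  ratio <- cfg$target_body_weight_kg / cfg$reference_body_weight_kg
  ch <- track$channels
  load_cols <- names(track$roles)[track$roles == "force"]
  ch[load_cols] <- ch[load_cols] * ratio
  extra <- track$extra
  if (!is.null(extra)) extra[] <- lapply(extra, function(v) v * ratio)
  load_case_track(track$adl, track$time_s, ch, track$frequency_hz,
                  frame = track$frame, periodised = track$periodised,
                  extra = extra)
}

# quintic Hermite segment matching value, first and second derivative at both
# ends; s in [0,1], derivatives already scaled by the segment length.
quintic_hermite <- function(s, y0, d0, dd0, y1, d1, dd1) {
  s2 <- s * s; s3 <- s2 * s; s4 <- s3 * s; s5 <- s4 * s
  h0 <- 1 - 10 * s3 + 15 * s4 - 6 * s5
  h1 <- s - 6 * s3 + 8 * s4 - 3 * s5
  h2 <- 0.5 * s2 - 1.5 * s3 + 1.5 * s4 - 0.5 * s5
  h3 <- 10 * s3 - 15 * s4 + 6 * s5
  h4 <- -4 * s3 + 7 * s4 - 3 * s5
  h5 <- 0.5 * s3 - s4 + 0.5 * s5
  h0 * y0 + h1 * d0 + h2 * dd0 + h3 * y1 + h4 * d1 + h5 * dd1
}

periodise_channel <- function(y, n_app, dt) {
  n <- length(y)
  h <- n_app * dt
  d_end <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  d_start <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  dd_end <- if (n >= 4) (2 * y[n] - 5 * y[n - 1] + 4 * y[n - 2] - y[n - 3]) / dt^2 else 0
  dd_start <- if (n >= 4) (2 * y[1] - 5 * y[2] + 4 * y[3] - y[4]) / dt^2 else 0
  s <- seq_len(n_app) / n_app
  app <- quintic_hermite(s, y[n], d_end * h, dd_end * h^2,
                         y[1], d_start * h, dd_start * h^2)
  app[n_app] <- y[1]  # exact periodicity for cyclic control
  c(y, app)
}

#' Harmonise a load-case cycle for cyclic control
#'
#' Cyclic (iteration-based) control of a joint simulator needs waveforms
#' whose start and end values match. The track is extended by
#' `extension_fraction` of its length with a quintic Hermite blend that meets
#' the old endpoint and the cycle start in value and slope (and estimated
#' curvature), so the output is C1-periodic. All original samples are kept
#' bitwise; the final sample is forced exactly equal to the first.
#'
#' @param track a [load_case_track()] with at least 4 samples.
#' @param extension_fraction fraction of the cycle appended (default 0.15).
#' @return The periodised [load_case_track()].
#' @export
periodise <- function(track, extension_fraction = 0.15) {
  stopifnot(inherits(track, "load_case_track"))
  if (!is.numeric(extension_fraction) || extension_fraction <= 0 ||
      extension_fraction >= 1) {
    stop("extension_fraction must lie in (0, 1)")
  }
  n <- length(track$time_s)
  if (n < 4L) stop("degenerate track: periodisation needs at least 4 samples")
  m <- as.integer(ceiling((1 + extension_fraction) * n))
  n_app <- m - n
  dt <- (track$time_s[n] - track$time_s[1]) / (n - 1)
  time_out <- track$time_s[1] + (seq_len(m) - 1) * dt
  time_out[seq_len(n)] <- track$time_s
  ch <- as.data.frame(lapply(track$channels, periodise_channel,
                             n_app = n_app, dt = dt))
  extra <- track$extra
  if (!is.null(extra)) {
    extra <- as.data.frame(lapply(extra, periodise_channel,
                                  n_app = n_app, dt = dt))
  }
  load_case_track(track$adl, time_out, ch, track$frequency_hz,
                  frame = track$frame, periodised = TRUE, extra = extra)
}

#' Full load-case preparation chain
#'
#' Prepares a raw source-frame load case for the simulator: body-weight
#' scaling, per-sample rigid re-registration of the kinematics and the load
#' wrench into the target implant frame, conversion to Grood-Suntay
#' components, and periodisation. The re-registered flexion and
#' axial-rotation moments (not part of the six controlled channels) are kept
#' as supplementary columns `fe_Nm` and `ei_Nm`.
#'
#' @param track a raw [load_case_track()] in the registration's source frame.
#' @param reg a [frame_registration()]; applied to both component frames.
#' @param cfg a [scaling_config()].
#' @param extension_fraction passed to [periodise()].
#' @param side knee side for the pose reconstruction.
#' @return A simulator-ready periodised [load_case_track()] in the target
#'   frame (Grood-Suntay components).
#' @export
prepare_load_case <- function(track, reg, cfg,
                              extension_fraction = 0.15,
                              side = "right") {
  stopifnot(inherits(track, "load_case_track"),
            inherits(reg, "frame_registration"),
            inherits(cfg, "scaling_config"))
  if (!identical(track$frame, reg$source_frame)) {
    stop(sprintf("stage 'register': track frame '%s' does not match registration source '%s'",
                 track$frame, reg$source_frame))
  }
  scaled <- tryCatch(scale_loads(track, cfg),
                     error = function(e) stop("stage 'scale': ", conditionMessage(e)))
  n <- length(scaled$time_s)
  ch <- scaled$channels
  out <- matrix(0, n, 6, dimnames = list(NULL, track_channel_names))
  extra <- matrix(0, n, 2, dimnames = list(NULL, c("fe_Nm", "ei_Nm")))
  for (i in seq_len(n)) {
    pose_i <- pose_from_jcs(jcs_coordinates(flexion_deg = ch$fe_deg[i],
                                            internal_rot_deg = ch$ei_deg[i]),
                            side = side)
    w_i <- wrench(force_N = c(ch$ap_N[i], ch$is_N[i], ch$ml_N[i]),
                  moment_Nm = c(ch$abad_Nm[i], 0, 0),
                  frame_id = track$frame, origin_mm = c(0, 0, 0))
    pose_t <- tryCatch(register_pose(pose_i, reg),
                       error = function(e) stop("stage 'register': ", conditionMessage(e)))
    w_t <- tryCatch(register_wrench(w_i, reg),
                    error = function(e) stop("stage 'register': ", conditionMessage(e)))
    w_t$frame_id <- "tibial"  # target implant frame moves with the tibia
    q <- tryCatch(jcs_from_pose(pose_t),
                  error = function(e) stop("stage 'jcs': ", conditionMessage(e)))
    g <- tryCatch(jcs_load_from_wrench(w_t, pose_t),
                  error = function(e) stop("stage 'jcs': ", conditionMessage(e)))
    out[i, ] <- c(q[["flexion_deg"]], q[["internal_rot_deg"]],
                  g[["ml_force_N"]], g[["ap_force_N"]], g[["is_force_N"]],
                  g[["adduction_moment_Nm"]])
    extra[i, ] <- c(g[["flexion_moment_Nm"]], g[["internal_rot_moment_Nm"]])
  }
  staged <- load_case_track(track$adl, scaled$time_s, as.data.frame(out),
                            track$frequency_hz, frame = reg$target_frame,
                            periodised = FALSE, extra = as.data.frame(extra))
  tryCatch(periodise(staged, extension_fraction),
           error = function(e) stop("stage 'periodise': ", conditionMessage(e)))
}
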