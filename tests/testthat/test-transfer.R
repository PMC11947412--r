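test_that("wrench re-expression matches hand values and preserves invariants", {
  # identity registration leaves the wrench untouched
  reg_id <- frame_registration(source_frame = "A", target_frame = "B")
  w <- wrench(c(10, -20, 30), c(1, 2, -3), frame_id = "A")
  w2 <- register_wrench(w, reg_id)
  expect_identical(w2$force_N, w$force_N)
  expect_identical(w2$moment_Nm, w$moment_Nm)

  # pure origin shift: r x F hand case
  reg <- frame_registration(diag(3), c(10, 0, 0), "A", "B")
  w <- wrench(c(0, 0, 100), c(0, 0, 0), frame_id = "A")
  expect_equal(register_wrench(w, reg)$moment_Nm, c(0, -1, 0))

  # rotation preserves the force norm
  reg65 <- default_registration()
  set.seed(5)
  for (i in 1:20) {
    w <- random_wrench(frame_id = "INNEX")
    w2 <- register_wrench(w, reg65)
    expect_equal(sqrt(sum(w2$force_N^2)), sqrt(sum(w$force_N^2)),
                 tolerance = 1e-12)
    # invariant F.M is frame independent
    expect_equal(sum(w2$force_N * w2$moment_Nm),
                 sum(w$force_N * (w$moment_Nm +
                                    kneetwin:::cross3(w$origin_mm, w$force_N) / 1000)),
                 tolerance = 1e-9)
  }
  expect_error(register_wrench(wrench(frame_id = "X"), reg65),
               "frame mismatch")
})

test_that("wrench re-expression agrees with the adjoint-matrix oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    axis <- stats::runif(3, -1, 1)
    reg <- frame_registration(rotation_about_axis(axis, stats::runif(1, -180, 180)),
                              stats::runif(3, -20, 20), "A", "B")
    w <- random_wrench(frame_id = "A", origin_mm = stats::runif(3, -5, 5))
    got <- register_wrench(w, reg)
    want <- adjoint_oracle(w, reg)
    scale <- max(abs(want), 1)
    worst <- max(worst, max(abs(c(got$force_N, got$moment_Nm) - want)) / scale)
  }
  expect_lt(worst, 1e-9)
})

test_that("registration then inverse registration is the identity", {
  set.seed(13)
  reg <- frame_registration(rotation_about_axis(c(1, 2, 3), 37),
                            c(4, -5, 6), "A", "B")
  inv <- kneetwin:::invert_registration(reg)
  for (i in 1:20) {
    w <- random_wrench(frame_id = "A")
    w$origin_mm <- c(0, 0, 0)
    back <- register_wrench(register_wrench(w, reg), inv)
    expect_equal(back$force_N, w$force_N, tolerance = 1e-12)
    expect_equal(back$moment_Nm, w$moment_Nm, tolerance = 1e-12)
    p <- random_pose()
    pb <- register_pose(register_pose(p, reg), inv)
    expect_equal(pb$rotation, p$rotation, tolerance = 1e-12)
    expect_equal(pb$translation, p$translation, tolerance = 1e-12)
  }
})

test_that("pose re-registration matches the homogeneous-matrix oracle", {
  set.seed(17)
  id <- frame_registration()
  p <- random_pose()
  p_id <- register_pose(p, id, id)
  expect_equal(p_id$rotation, p$rotation)
  expect_equal(p_id$translation, p$translation)

  # pure femoral-side rotation: new rotation is Q^T R
  Q <- rotation_about_axis(c(0, 1, 0), 25)
  reg_f <- frame_registration(Q, c(0, 0, 0))
  p2 <- register_pose(p, reg_f, id)
  expect_equal(p2$rotation, t(Q) %*% p$rotation, tolerance = 1e-12)

  for (i in 1:50) {
    rf <- frame_registration(rotation_about_axis(stats::runif(3, -1, 1),
                                                 stats::runif(1, -90, 90)),
                             stats::runif(3, -10, 10))
    rt <- frame_registration(rotation_about_axis(stats::runif(3, -1, 1),
                                                 stats::runif(1, -90, 90)),
                             stats::runif(3, -10, 10))
    p <- random_pose()
    got <- register_pose(p, rf, rt)
    H <- homogeneous_oracle(p, rf, rt)
    expect_equal(got$rotation, H[1:3, 1:3], tolerance = 1e-9)
    expect_equal(got$translation, as.numeric(H[1:3, 4]), tolerance = 1e-9)
  }
})

test_that("default implant registration carries the 6.5 degree slope tilt", {
  reg <- default_registration()
  aa <- kneetwin:::axis_angle(reg$rotation)
  expect_equal(aa$angle_deg, 6.5, tolerance = 1e-12)
  expect_equal(abs(aa$axis), c(0, 0, 1), tolerance = 1e-12)
  expect_lte(sqrt(sum(reg$origin_shift_mm^2)), 1)
})

test_that("body-weight scaling touches only the load channels", {
  tr <- generate_load_case("level_walking", 64, seed = 3)
  same <- scale_loads(tr, scaling_config(75, 75))
  expect_identical(same$channels, tr$channels)

  sc <- scale_loads(tr, scaling_config(reference_body_weight_kg = 100,
                                       target_body_weight_kg = 75))
  expect_identical(sc$channels$fe_deg, tr$channels$fe_deg)
  expect_identical(sc$channels$ei_deg, tr$channels$ei_deg)
  expect_equal(sc$channels$is_N, 0.75 * tr$channels$is_N)
  expect_equal(sc$channels$abad_Nm, 0.75 * tr$channels$abad_Nm)
  expect_identical(sc$frequency_hz, tr$frequency_hz)
  # -2000 N axial sample scales to -1500 N
  tr2 <- tr
  tr2$channels$is_N[5] <- -2000
  expect_equal(scale_loads(tr2, scaling_config(100, 75))$channels$is_N[5],
               -1500)
  expect_error(scaling_config(-1, 75), "positive")
})

test_that("scaling commutes with wrench re-expression", {
  reg <- default_registration()
  ratio <- 0.75
  set.seed(29)
  for (i in 1:20) {
    w <- random_wrench(frame_id = "INNEX")
    w$origin_mm <- c(0, 0, 0)
    a <- register_wrench(wrench(ratio * w$force_N, ratio * w$moment_Nm,
                                "INNEX"), reg)
    b <- register_wrench(w, reg)
    expect_equal(a$force_N, ratio * b$force_N, tolerance = 1e-12)
    expect_equal(a$moment_Nm, ratio * b$moment_Nm, tolerance = 1e-12)
  }
})

test_that("periodisation meets the endpoint and duration contract", {
  # linear ramp over 100 samples -> 115 samples, wrapped endpoint
  t <- seq(0, 1.6, length.out = 100)
  ramp <- seq(0, 10, length.out = 100)
  ch <- data.frame(fe_deg = ramp, ei_deg = ramp / 2, ml_N = -ramp,
                   ap_N = 2 * ramp, is_N = -100 - ramp, abad_Nm = ramp / 10)
  tr <- load_case_track("squat", t, ch, frequency_hz = 1 / 1.6)
  out <- periodise(tr, 0.15)
  expect_identical(length(out$time_s), 115L)
  for (cn in names(out$channels)) {
    y <- out$channels[[cn]]
    expect_identical(y[1:100], ch[[cn]])         # originals kept bitwise
    expect_identical(y[115], y[1])               # exact endpoint equality
  }
  dt <- t[2] - t[1]
  dur_in <- t[100] - t[1]
  dur_out <- out$time_s[115] - out$time_s[1]
  expect_lte(abs(dur_out - 1.15 * dur_in), dt + 1e-12)
  expect_true(out$periodised)

  # constant channel stays constant
  ch2 <- as.data.frame(lapply(ch, function(x) rep(3, 100)))
  out2 <- periodise(load_case_track("squat", t, ch2, 0.625))
  expect_equal(out2$channels$fe_deg, rep(3, 115), tolerance = 1e-9)

  expect_error(periodise(tr, 0), "extension_fraction")
  short <- load_case_track("squat", t[1:3], ch[1:3, ], 0.625)
  expect_error(periodise(short), "at least 4 samples")
})

test_that("periodisation is C1 at the junction and bounded for periodic input", {
  n <- 200
  t <- seq(0, 1, length.out = n)
  y <- sin(2 * pi * t)
  ch <- data.frame(fe_deg = y, ei_deg = y, ml_N = y, ap_N = y, is_N = y - 2,
                   abad_Nm = y)
  tr <- load_case_track("level_walking", t, ch, 1)
  out <- periodise(tr)
  yo <- out$channels$fe_deg
  m <- length(yo)
  dt <- t[2] - t[1]
  # appended segment of an already-periodic channel stays inside its envelope
  expect_true(all(yo >= min(y) - 1e-9 & yo <= max(y) + 1e-9))
  # slope continuity at the old end and at the wrap, against the true 2*pi
  slope_end <- (yo[n + 1] - yo[n]) / dt
  slope_wrap <- (yo[1] - yo[m - 1]) / dt   # y[m] == y[1]
  expect_lt(abs(slope_end - 2 * pi), 0.05 * 2 * pi)
  expect_lt(abs(slope_wrap - 2 * pi), 0.05 * 2 * pi)
  # re-harmonising a harmonised track keeps endpoints exactly equal
  out2 <- periodise(out)
  for (cn in names(out2$channels)) {
    y2 <- out2$channels[[cn]]
    expect_identical(abs(y2[length(y2)] - y2[1]), 0)
  }
})

test_that("the preparation chain composes its stages in order", {
  # identity registration + unit scaling on an already periodic track equals
  # plain conversion to joint coordinates on the original samples
  id <- frame_registration(source_frame = "INNEX", target_frame = "INNEX")
  cfg <- scaling_config(75, 75)
  tr <- generate_load_case("squat", 64, seed = 2,
                           overrides = list(endpoint_mismatch = 0))
  out <- prepare_load_case(tr, id, cfg)
  n <- length(tr$time_s)
  for (i in c(1, 17, 33, n)) {
    pose_i <- pose_from_jcs(jcs_coordinates(
      flexion_deg = tr$channels$fe_deg[i],
      internal_rot_deg = tr$channels$ei_deg[i]))
    w_i <- wrench(c(tr$channels$ap_N[i], tr$channels$is_N[i],
                    tr$channels$ml_N[i]),
                  c(tr$channels$abad_Nm[i], 0, 0), frame_id = "tibial")
    g <- jcs_load_from_wrench(w_i, pose_i)
    expect_equal(out$channels$fe_deg[i], tr$channels$fe_deg[i],
                 tolerance = 1e-9)
    expect_equal(out$channels$ml_N[i], g[["ml_force_N"]], tolerance = 1e-9)
    expect_equal(out$channels$ap_N[i], g[["ap_force_N"]], tolerance = 1e-9)
    expect_equal(out$channels$is_N[i], g[["is_force_N"]], tolerance = 1e-9)
    expect_equal(out$channels$abad_Nm[i], g[["adduction_moment_Nm"]],
                 tolerance = 1e-9)
  }

  # synthetic fixture: all four force-controlled channels end up periodic
  tr2 <- generate_load_case("downhill_walking", 64, seed = 4)
  out2 <- prepare_load_case(tr2, default_registration(), scaling_config(75))
  m <- length(out2$time_s)
  for (cn in c("ml_N", "ap_N", "is_N", "abad_Nm")) {
    expect_identical(out2$channels[[cn]][m], out2$channels[[cn]][1])
  }
  expect_identical(out2$frame, "PFC_SIGMA")

  # a 1 mm origin shift under ~2000 N axial load moves the flexion-moment
  # channel by at most |r x F| = 2 N m and leaves force magnitudes unchanged
  tr3 <- generate_load_case("squat", 64, seed = 2,
                            overrides = list(endpoint_mismatch = 0))
  reg_shift <- frame_registration(diag(3), c(1, 0, 0),
                                  "INNEX", "INNEX")
  out_id <- prepare_load_case(tr3, id, cfg)
  out_sh <- prepare_load_case(tr3, reg_shift, cfg)
  dmom <- abs(out_sh$extra$fe_Nm - out_id$extra$fe_Nm)
  bound <- 1e-3 * sqrt(tr3$channels$ml_N^2 + tr3$channels$ap_N^2 +
                         tr3$channels$is_N^2)
  n3 <- length(tr3$time_s)
  expect_true(all(dmom[1:n3] <= bound + 1e-9))
  expect_gt(max(dmom[1:n3]), 0)
  for (i in c(1, 33)) {
    f_id <- c(out_id$channels$ml_N[i], out_id$channels$ap_N[i],
              out_id$channels$is_N[i])
    f_sh <- c(out_sh$channels$ml_N[i], out_sh$channels$ap_N[i],
              out_sh$channels$is_N[i])
    expect_equal(sqrt(sum(f_sh^2)), sqrt(sum(f_id^2)), tolerance = 1e-9)
  }

  # stage names propagate in errors
  bad <- tr3
  bad$frame <- "OTHER"
  expect_error(prepare_load_case(bad, id, cfg), "register")
})
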