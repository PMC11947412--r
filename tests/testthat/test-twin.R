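test_that("penalty contact reproduces its closed-form geometry", {
  params <- contact_params(penalty_stiffness_N_mm = 1e4, exponent = 1)
  surf <- plane_surface()
  # separated surfaces -> zero wrench
  cw <- contact_wrench(rigid_pose(), surf, params)
  expect_identical(cw$wrench$force_N, c(0, 0, 0))
  expect_identical(cw$penetration_mm[["medial"]], 0)
  # sphere on plane with penetration 0.1 mm and k_c = 1e4, n = 1 -> 1000 N
  pose <- rigid_pose(translation = c(0, 0.6, 0))  # gap 0.5 + 0.1
  cw <- contact_wrench(pose, surf, params)
  expect_equal(cw$penetration_mm[["medial"]], 0.1, tolerance = 1e-12)
  expect_equal(cw$normal_force_N[["medial"]], 1000, tolerance = 1e-9)
  expect_equal(cw$wrench$force_N, c(0, -1000, 0), tolerance = 1e-9)
  # symmetric two-condyle dish contact: equal penetrations, no varus-valgus
  # moment about the midline
  surf2 <- toy_surfaces()
  pose2 <- rigid_pose(translation = c(0, 1.0, 0))
  cw2 <- contact_wrench(pose2, surf2, contact_params())
  expect_equal(cw2$penetration_mm[["medial"]], cw2$penetration_mm[["lateral"]],
               tolerance = 1e-12)
  expect_lt(abs(cw2$wrench$moment_Nm[1]), 1e-9)
  expect_lt(abs(cw2$wrench$force_N[3]), 1e-9)
})

test_that("equilibrium matches analytic contact with ligaments off", {
  params <- contact_params(penalty_stiffness_N_mm = 5000, exponent = 1)
  surf <- plane_surface()
  app <- slack_apparatus()
  for (F in c(100, 400, 1000, 2000, 3000)) {
    st <- solve_equilibrium_step(c(fe_deg = 0, ei_deg = 0),
                                 jcs_load(is_force_N = -F), app, surf, params,
                                 tol_force_N = 1e-3, tol_moment_Nm = 1e-4)
    expect_true(st$converged)
    pen <- st$coords[["is_mm"]] - 0.5   # neutral gap is 0.5 mm
    expect_lt(abs(pen - F / 5000), 1e-8)
  }
})

test_that("symmetric configurations have symmetric equilibria", {
  surf <- toy_surfaces()
  app <- set_reference_pose(symmetric_apparatus(), rigid_pose())
  st <- solve_equilibrium_step(c(fe_deg = 0, ei_deg = 0),
                               jcs_load(is_force_N = -1000), app, surf,
                               contact_params(), tol_force_N = 1e-2,
                               tol_moment_Nm = 1e-3)
  expect_true(st$converged)
  expect_lt(abs(st$coords[["ml_mm"]]), 1e-6)
  expect_lt(abs(st$coords[["ap_mm"]]), 1e-6)
  expect_lt(abs(st$coords[["adduction_deg"]]), 1e-6)
  # reported residuals are recomputed from the returned pose
  pose <- pose_from_jcs(st$coords)
  cw <- contact_wrench(pose, surf, contact_params())
  lw <- apparatus_wrench(app, pose)
  tot <- jcs_load_from_wrench(wrench(cw$wrench$force_N + lw$force_N,
                                     cw$wrench$moment_Nm + lw$moment_Nm,
                                     "femoral", pose$translation), pose)
  expect_equal(max(abs(c(tot[["ml_force_N"]], tot[["ap_force_N"]],
                         tot[["is_force_N"]] + 1000))),
               st$residual_force_N, tolerance = 1e-9)
})

test_that("an anterior-pulling strand shifts the equilibrium anteriorly", {
  surf <- toy_surfaces()
  params <- contact_params()
  base <- set_reference_pose(symmetric_apparatus(), rigid_pose())
  st0 <- solve_equilibrium_step(c(fe_deg = 0, ei_deg = 0),
                                jcs_load(is_force_N = -1000), base, surf,
                                params)
  with_ant <- symmetric_apparatus()
  with_ant$strands$anterior <- ligament_strand(
    "anterior", "capsular", c(45, 0, 0), c(0, 0, 0), 4000, 0.05)
  with_ant <- set_reference_pose(ligament_apparatus(unname(with_ant$strands)),
                                 rigid_pose())
  st1 <- solve_equilibrium_step(c(fe_deg = 0, ei_deg = 0),
                                jcs_load(is_force_N = -1000), with_ant, surf,
                                params)
  expect_true(st1$converged)
  expect_gt(st1$coords[["ap_mm"]], st0$coords[["ap_mm"]] + 0.05)
})

test_that("running a constant-target track reproduces the single-step solve", {
  surf <- toy_surfaces()
  params <- contact_params()
  app <- set_reference_pose(default_apparatus(1), rigid_pose())
  n <- 33
  ch <- data.frame(fe_deg = rep(20, n), ei_deg = 0, ml_N = 0, ap_N = -50,
                   is_N = -800, abad_Nm = 1)
  tr <- load_case_track("squat", seq(0, 5, length.out = n), ch, 0.2,
                        periodised = TRUE)
  res <- run_load_case(tr, app, surf, params, cycles = 1)
  st <- solve_equilibrium_step(c(fe_deg = 20, ei_deg = 0),
                               jcs_load(ap_force_N = -50, is_force_N = -800,
                                        adduction_moment_Nm = 1),
                               app, surf, params)
  expect_true(all(res$steps$converged))
  for (cn in c("adduction_deg", "ml_mm", "ap_mm", "is_mm")) {
    expect_equal(res$steps[[cn]], rep(st$coords[[cn]], n), tolerance = 1e-6)
  }
  # unreferenced apparatus and raw tracks are refused
  expect_error(run_load_case(tr, default_apparatus(1), surf, params),
               "set_reference_pose")
  raw <- tr
  raw$periodised <- FALSE
  expect_error(run_load_case(raw, app, surf, params), "not periodised")
})

test_that("the quasi-static run is deterministic and cycle-periodic", {
  surf <- toy_surfaces()
  params <- contact_params()
  app <- set_reference_pose(default_apparatus(1), rigid_pose())
  tr <- prepare_load_case(generate_load_case("squat", 40, seed = 1),
                          default_registration(), scaling_config(75))
  r1 <- run_load_case(tr, app, surf, params, cycles = 2)
  r2 <- run_load_case(tr, app, surf, params, cycles = 2)
  expect_identical(r1$steps, r2$steps)        # bitwise determinism
  expect_true(all(r1$steps$converged))
  expect_lt(r1$cycle_change, 1e-6)            # no memory in the twin
})

test_that("mean axial load is the time-weighted cycle mean", {
  n <- 101
  t <- seq(0, 2, length.out = n)
  mk <- function(is_N) {
    load_case_track("squat", t,
                    data.frame(fe_deg = 0, ei_deg = 0, ml_N = 0, ap_N = 0,
                               is_N = is_N, abad_Nm = 0), 0.5)
  }
  expect_equal(mean_axial_load(mk(rep(-1000, n))), -1000)
  # zero-mean sinusoid over an integer number of periods (trapezoid exact
  # at the wrap since the endpoints coincide)
  expect_equal(mean_axial_load(mk(-1000 + 500 * sin(2 * pi * t))), -1000,
               tolerance = 1e-9)
  # piecewise-linear hump: trapezoid equals the analytic integral exactly
  y <- -approx(c(0, 0.5, 2), c(0, 600, 0), xout = t)$y
  tr <- mk(y)
  analytic <- -0.5 * 600 * 2 / 2   # triangle area / duration
  expect_equal(mean_axial_load(tr), analytic, tolerance = 1e-9)
})

test_that("compliance compensation shifts the reference axially by c * mean load", {
  app <- ligament_apparatus(list(
    ligament_strand("v", "medial", c(0, 50, 0), c(0, 0, 0), 1000, 0.02)))
  n <- 65
  t <- seq(0, 1, length.out = n)
  mk <- function(is_N) {
    load_case_track("squat", t,
                    data.frame(fe_deg = 0, ei_deg = 0, ml_N = 0, ap_N = 0,
                               is_N = is_N, abad_Nm = 0), 1)
  }
  tr <- mk(rep(-1200, n))
  # c = 0: identical to plain referencing
  a0 <- apply_compliance_compensation(app, tr, machine_compliance(0))
  expect_identical(a0$strands$v$reference_length_mm,
                   set_reference_pose(app, rigid_pose())$strands$v$reference_length_mm)
  # c > 0 under compression: the vertical strand is referenced longer by
  # exactly c * |mean load|
  cc <- 2e-4
  a1 <- apply_compliance_compensation(app, tr, machine_compliance(cc))
  expect_equal(a1$strands$v$reference_length_mm, 50 + cc * 1200,
               tolerance = 1e-9)
  # equal mean loads give identical compensated apparatus
  tr2 <- mk(-1200 + 300 * sin(2 * pi * t))
  a2 <- apply_compliance_compensation(app, tr2, machine_compliance(cc))
  expect_equal(a2$strands$v$reference_length_mm,
               a1$strands$v$reference_length_mm, tolerance = 1e-9)
  expect_error(machine_compliance(-1), ">= 0")
})

test_that("contact footprints match the chord-circle area", {
  surf <- plane_surface()
  # empty trajectory -> zero area
  fp0 <- contact_footprint(list(), surf, 0.5)
  expect_identical(fp0$medial$area_mm2, 0)
  # static sphere-on-plane: area within 2% of pi (2 R d - d^2)
  delta <- 0.1
  pose <- rigid_pose(translation = c(0, 0.5 + delta, 0))
  fp <- contact_footprint(list(pose), surf, grid_res_mm = 0.1)
  analytic <- pi * (2 * 25 * delta - delta^2)
  expect_lt(abs(fp$medial$area_mm2 - analytic) / analytic, 0.02)
  expect_equal(unname(fp$medial$centroid_mm), c(0, 0), tolerance = 0.1)
})

test_that("a higher medial load share gives a medial-dominant footprint", {
  surf <- toy_surfaces()
  # small adduction tilts load onto the medial condyle over the trajectory
  poses <- lapply(seq(0, 0.3, length.out = 8), function(ad) {
    pose_from_jcs(jcs_coordinates(flexion_deg = 2 * ad, adduction_deg = ad,
                                  is_mm = 1.0))
  })
  med_share <- vapply(poses, function(p) {
    cw <- contact_wrench(p, surf, contact_params())
    cw$normal_force_N[["medial"]] -
      cw$normal_force_N[["lateral"]]
  }, numeric(1))
  expect_true(all(med_share >= 0))
  fp <- contact_footprint(poses, surf, grid_res_mm = 0.25)
  expect_gte(fp$medial$area_mm2, fp$lateral$area_mm2)
  expect_gt(fp$medial$area_mm2, 0)
})

test_that("flexion-binned comparison separates phases and bins", {
  surf <- toy_surfaces()
  params <- contact_params()
  app <- set_reference_pose(default_apparatus(1), rigid_pose())
  tr <- prepare_load_case(generate_load_case("squat", 40, seed = 1),
                          default_registration(), scaling_config(75))
  res <- run_load_case(tr, app, surf, params, cycles = 1)
  # compared with itself: all deltas are zero
  cmp <- flexion_binned_comparison(res, res, bin_deg = 10)
  expect_true(all(cmp$d_ap_mm == 0))
  expect_true(all(cmp$d_adduction_deg == 0))
  expect_true(all(cmp$d_is_force_N == 0))
  # a monotone flexion ramp has no extension phase and spans all bins
  n <- 41
  ch <- data.frame(fe_deg = seq(0, 80, length.out = n), ei_deg = 0, ml_N = 0,
                   ap_N = 0, is_N = -500, abad_Nm = 0)
  ramp <- load_case_track("squat", seq(0, 5, length.out = n), ch, 0.2,
                          periodised = TRUE)
  r <- run_load_case(ramp, app, surf, params, cycles = 1)
  cmp2 <- flexion_binned_comparison(r, r, bin_deg = 10)
  expect_true(all(cmp2$phase == "flexion"))
  expect_identical(sum(cmp2$n), as.integer(n))
  # results from different tracks are refused
  other <- run_load_case(tr, app, surf, params, cycles = 1)
  other$adl <- "squat"
  other$steps <- other$steps[-1, ]
  expect_error(flexion_binned_comparison(res, other), "different tracks")
})
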