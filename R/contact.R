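#' Toy articulating surfaces: two femoral spheres on tibial dishes or a plane
#'
#' A deliberately simple, analytic surrogate for condylar implant surfaces:
#' each femoral condyle is a sphere; the tibial side is either a concave
#' spherical dish per condyle (radius at least the sphere radius) or a flat
#' plateau. Geometry is expressed in the component frames (x anterior,
#' y proximal, z lateral; mm).
#'
#' @param femoral_radius_mm femoral condyle sphere radius.
#' @param femoral_centers_mm 2x3 matrix of sphere centres in the femoral
#'   frame, rows = (medial, lateral).
#' @param tibial_type `"dish"` or `"plane"`.
#' @param dish_radius_mm tibial dish radius (>= sphere radius), used for
#'   `"dish"`.
#' @param dish_centers_mm 2x3 matrix of dish centres in the tibial frame.
#' @param plane_y_mm height of the flat plateau in the tibial frame, used for
#'   `"plane"`.
#' @param condyles which condyles exist; `c("medial", "lateral")` by default
#'   (a single-condyle surface is useful for analytic checks).
#' @return An object of class `contact_surface`.
#' @export
contact_surface <- function(femoral_radius_mm,
                            femoral_centers_mm,
                            tibial_type = c("dish", "plane"),
                            dish_radius_mm = NULL,
                            dish_centers_mm = NULL,
                            plane_y_mm = NULL,
                            condyles = c("medial", "lateral")) {
  tibial_type <- match.arg(tibial_type)
  if (!is.numeric(femoral_radius_mm) || femoral_radius_mm <= 0) {
    stop("femoral sphere radius must be positive")
  }
  femoral_centers_mm <- matrix(as.numeric(femoral_centers_mm),
                               ncol = 3, byrow = FALSE)
  if (nrow(femoral_centers_mm) != length(condyles)) {
    stop("femoral_centers_mm must have one row per condyle")
  }
  if (tibial_type == "dish") {
    if (is.null(dish_radius_mm) || dish_radius_mm < femoral_radius_mm) {
      stop("dish radius must be at least the femoral sphere radius")
    }
    dish_centers_mm <- matrix(as.numeric(dish_centers_mm), ncol = 3)
    if (nrow(dish_centers_mm) != length(condyles)) {
      stop("dish_centers_mm must have one row per condyle")
    }
  } else {
    if (is.null(plane_y_mm) || !is.numeric(plane_y_mm)) {
      stop("plane_y_mm is required for a plane tibial surface")
    }
  }
  structure(list(femoral_radius_mm = femoral_radius_mm,
                 femoral_centers_mm = femoral_centers_mm,
                 tibial_type = tibial_type,
                 dish_radius_mm = dish_radius_mm,
                 dish_centers_mm = dish_centers_mm,
                 plane_y_mm = plane_y_mm,
                 condyles = condyles),
            class = "contact_surface")
}

#' Penalty contact parameters
#'
#' @param penalty_stiffness_N_mm stiffness k_c; the normal force is
#'   `k_c * penetration^exponent` (N with penetration in mm).
#' @param exponent penetration exponent n >= 1 (1 = linear penalty).
#' @param frictionless logical; the twin models a lubricated, frictionless
#'   articulation (the only supported mode).
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(penalty_stiffness_N_mm = 5000, exponent = 1,
                           frictionless = TRUE) {
  if (!is.numeric(penalty_stiffness_N_mm) || penalty_stiffness_N_mm <= 0) {
    stop("penalty stiffness must be positive")
  }
  if (!is.numeric(exponent) || exponent < 1) stop("exponent must be >= 1")
  if (!isTRUE(frictionless)) stop("only frictionless contact is implemented")
  structure(list(penalty_stiffness_N_mm = penalty_stiffness_N_mm,
                 exponent = exponent, frictionless = TRUE),
            class = "contact_params")
}

# per-condyle penetration geometry in the tibial frame; returns NULL when
# separated, else list(delta, u (force direction on the tibia), p_c (contact
# point), patch_center (x,z), patch_radius)
condyle_contact <- function(sphere_center_t, surface, ci) {
  rf <- surface$femoral_radius_mm
  if (surface$tibial_type == "plane") {
    delta <- surface$plane_y_mm - (sphere_center_t[2] - rf)
    if (delta <= 0) return(NULL)
    a2 <- max(2 * rf * delta - delta^2, 0)
    list(delta = delta, u = c(0, -1, 0),
         p_c = c(sphere_center_t[1], surface$plane_y_mm, sphere_center_t[3]),
         patch_center = sphere_center_t[c(1, 3)],
         patch_radius = sqrt(a2))
  } else {
    cd <- surface$dish_centers_mm[ci, ]
    rd <- surface$dish_radius_mm
    v <- sphere_center_t - cd
    d <- norm3(v)
    delta <- d - (rd - rf)
    if (delta <= 0 || d == 0) return(NULL)
    u <- v / d
    # intersection circle of the two spheres (inner sphere poking through
    # the concave dish); degenerates to the full conforming band as rd -> rf
    x0 <- (d^2 + rd^2 - rf^2) / (2 * d)
    a2 <- max(rd^2 - x0^2, 0)
    p3 <- cd + x0 * u
    list(delta = delta, u = u, p_c = cd + rd * u,
         patch_center = p3[c(1, 3)], patch_radius = sqrt(a2))
  }
}

#' Contact wrench between the toy surfaces
#'
#' Computes per-condyle penetrations from the analytic sphere-dish (or
#' sphere-plane) geometry, applies the penalty law along the contact normal,
#' and sums the loads on the tibia into a wrench about the tibial origin.
#' Separated condyles contribute zero.
#'
#' @param pose the current [rigid_pose()].
#' @param surface a [contact_surface()].
#' @param params a [contact_params()].
#' @return A list: `wrench` (femoral-frame [wrench()] about the tibial
#'   origin), `penetration_mm` and `normal_force_N` (named per condyle).
#' @export
contact_wrench <- function(pose, surface, params) {
  stopifnot(inherits(pose, "rigid_pose"), inherits(surface, "contact_surface"),
            inherits(params, "contact_params"))
  R <- pose$rotation
  t <- pose$translation
  F_t <- c(0, 0, 0)
  M_t <- c(0, 0, 0)
  pen <- stats::setNames(numeric(length(surface$condyles)), surface$condyles)
  nf <- pen
  for (ci in seq_along(surface$condyles)) {
    s_t <- as.numeric(t(R) %*% (surface$femoral_centers_mm[ci, ] - t))
    cc <- condyle_contact(s_t, surface, ci)
    if (is.null(cc)) next
    f <- params$penalty_stiffness_N_mm * cc$delta^params$exponent
    pen[ci] <- cc$delta
    nf[ci] <- f
    Fv <- f * cc$u
    F_t <- F_t + Fv
    M_t <- M_t + cross3(cc$p_c, Fv) / 1000
  }
  list(wrench = wrench(force_N = as.numeric(R %*% F_t),
                       moment_Nm = as.numeric(R %*% M_t),
                       frame_id = "femoral", origin_mm = t),
       penetration_mm = pen, normal_force_N = nf)
}

#' Contact footprint of a kinematic trajectory
#'
#' Rasterises the analytic contact-patch boundary of every pose onto a grid
#' on the tibial surface and unions the marked cells per condyle. This is a
#' qualitative analogue of a scanning-spray footprint, not a stress map.
#'
#' @param poses list of [rigid_pose()] objects (may be empty).
#' @param surface a [contact_surface()].
#' @param grid_res_mm grid cell size, mm.
#' @return A list per condyle with `area_mm2`, `centroid_mm` (x, z in the
#'   tibial frame; `NA` for an empty footprint) and `n_cells`.
#' @export
contact_footprint <- function(poses, surface, grid_res_mm = 0.5) {
  stopifnot(inherits(surface, "contact_surface"))
  if (!is.numeric(grid_res_mm) || grid_res_mm <= 0) {
    stop("grid_res_mm must be positive")
  }
  out <- list()
  for (ci in seq_along(surface$condyles)) {
    # grid extent around the condyle centre
    centre <- if (surface$tibial_type == "dish") {
      surface$dish_centers_mm[ci, c(1, 3)]
    } else {
      # plane: centre the grid under the neutral sphere position
      surface$femoral_centers_mm[ci, c(1, 3)]
    }
    half <- surface$femoral_radius_mm + 2
    gx <- seq(centre[1] - half, centre[1] + half, by = grid_res_mm)
    gz <- seq(centre[2] - half, centre[2] + half, by = grid_res_mm)
    marked <- matrix(FALSE, length(gx), length(gz))
    for (pose in poses) {
      s_t <- as.numeric(t(pose$rotation) %*%
                          (surface$femoral_centers_mm[ci, ] - pose$translation))
      cc <- condyle_contact(s_t, surface, ci)
      if (is.null(cc) || cc$patch_radius <= 0) next
      dx2 <- (gx - cc$patch_center[1])^2
      dz2 <- (gz - cc$patch_center[2])^2
      marked <- marked | outer(dx2, dz2, `+`) <= cc$patch_radius^2
    }
    n_cells <- sum(marked)
    centroid <- if (n_cells > 0) {
      idx <- which(marked, arr.ind = TRUE)
      c(x = mean(gx[idx[, 1]]), z = mean(gz[idx[, 2]]))
    } else {
      c(x = NA_real_, z = NA_real_)
    }
    out[[surface$condyles[ci]]] <- list(area_mm2 = n_cells * grid_res_mm^2,
                                        centroid_mm = centroid,
                                        n_cells = n_cells)
  }
  out
}
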