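#' Parameters of the nonlinear ligament force law
#'
#' Point-to-point ligament strands follow a toe-region law: zero force for
#' negative strain, a quadratic rise up to twice the toe strain, and a linear
#' regime beyond. The toe strain defaults to 3% (the value used by the
#' six-DOF joint simulator this package emulates).
#'
#' Two strain definitions are supported. The default `"blankevoort"` model
#' measures strain relative to the zero-load length `lr / (1 + er)`:
#' `eps = (l * (1 + er) - lr) / lr`, which reaches zero (slack) when the
#' strand shortens below its zero-load length. The `"as_printed"` variant
#' `eps = er * l / lr` rescales the reference strain by the length ratio; it
#' never crosses zero for a positive reference strain and is retained for
#' fidelity testing only.
#'
#' @param toe_strain toe-region strain parameter (dimensionless, > 0).
#' @param strain_model `"blankevoort"` (default) or `"as_printed"`.
#' @return An object of class `ligament_law`.
#' @export
ligament_law <- function(toe_strain = 0.03,
                         strain_model = c("blankevoort", "as_printed")) {
  strain_model <- match.arg(strain_model)
  if (!is.numeric(toe_strain) || toe_strain <= 0) {
    stop("toe_strain must be positive")
  }
  structure(list(toe_strain = toe_strain, strain_model = strain_model),
            class = "ligament_law")
}

ligament_groups <- c("capsular", "medial", "lateral", "PCL")

#' A single point-to-point ligament strand
#'
#' @param name strand label.
#' @param group one of `"capsular"`, `"medial"`, `"lateral"`, `"PCL"`.
#' @param origin_mm femoral-frame attachment point, mm.
#' @param insertion_mm tibial-frame attachment point, mm.
#' @param stiffness_N stiffness k in N per unit strain (so k * eps is a
#'   force in N). Inputs quoted in N per percent strain must be multiplied
#'   by 100 first; see [read_apparatus()].
#' @param reference_strain pre-tension strain at the reference pose
#'   (dimensionless).
#' @return An object of class `ligament_strand`. The reference length is
#'   unset until [set_reference_pose()] is called on the apparatus.
#' @export
ligament_strand <- function(name, group, origin_mm, insertion_mm,
                            stiffness_N, reference_strain = 0) {
  group <- match.arg(group, ligament_groups)
  origin_mm <- unname(as.numeric(origin_mm))
  insertion_mm <- unname(as.numeric(insertion_mm))
  stopifnot(length(origin_mm) == 3L, length(insertion_mm) == 3L)
  if (!is.numeric(stiffness_N) || stiffness_N <= 0) {
    stop(sprintf("strand '%s': stiffness must be positive", name))
  }
  structure(list(name = as.character(name), group = group,
                 origin_mm = origin_mm, insertion_mm = insertion_mm,
                 stiffness_N = stiffness_N,
                 reference_strain = reference_strain,
                 reference_length_mm = NA_real_),
            class = "ligament_strand")
}

#' A virtual ligament apparatus
#'
#' An ordered collection of ligament strands sharing one force law, plus the
#' reference pose at which strand reference lengths were recorded.
#'
#' @param strands list of [ligament_strand()] objects.
#' @param law a [ligament_law()].
#' @return An object of class `ligament_apparatus`.
#' @export
ligament_apparatus <- function(strands, law = ligament_law()) {
  stopifnot(is.list(strands), length(strands) >= 1L,
            all(vapply(strands, inherits, logical(1), "ligament_strand")),
            inherits(law, "ligament_law"))
  names(strands) <- vapply(strands, `[[`, character(1), "name")
  if (anyDuplicated(names(strands))) stop("strand names must be unique")
  structure(list(strands = strands, law = law, reference_pose = NULL),
            class = "ligament_apparatus")
}

#' @export
print.ligament_apparatus <- function(x, ...) {
  groups <- vapply(x$strands, `[[`, character(1), "group")
  cat("ligament_apparatus:", length(x$strands), "strands (",
      paste(sprintf("%s: %d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n")
  cat("  strain model:", x$law$strain_model,
      "| toe strain:", x$law$toe_strain,
      "| referenced:", !is.null(x$reference_pose), "\n")
  invisible(x)
}

strand_length <- function(strand, pose) {
  p_ins <- as.numeric(pose$rotation %*% strand$insertion_mm) + pose$translation
  norm3(strand$origin_mm - p_ins)
}

#' Record strand reference lengths at a known joint pose
#'
#' The reference pose (usually full extension) is the posture at which each
#' strand's pre-tension (reference strain) is defined; this computes and
#' stores each strand's origin-insertion distance at that pose.
#'
#' @param app a [ligament_apparatus()].
#' @param pose the reference [rigid_pose()].
#' @return The referenced apparatus (the input is not modified).
#' @export
set_reference_pose <- function(app, pose) {
  stopifnot(inherits(app, "ligament_apparatus"), inherits(pose, "rigid_pose"))
  app$strands <- lapply(app$strands, function(s) {
    lr <- strand_length(s, pose)
    if (lr <= .Machine$double.eps) {
      stop(sprintf("strand '%s': coincident attachment points at the reference pose",
                   s$name))
    }
    s$reference_length_mm <- lr
    s
  })
  app$reference_pose <- pose
  app
}

#' Current strain of a ligament strand
#'
#' @param strand a referenced [ligament_strand()].
#' @param pose the current [rigid_pose()].
#' @param law a [ligament_law()] selecting the strain model.
#' @return Dimensionless strain; equals the reference strain when the strand
#'   is at its reference length under either model.
#' @export
strand_strain <- function(strand, pose, law = ligament_law()) {
  lr <- strand$reference_length_mm
  if (is.na(lr)) {
    stop(sprintf("strand '%s': reference length not initialised; call set_reference_pose() first",
                 strand$name))
  }
  l <- strand_length(strand, pose)
  er <- strand$reference_strain
  switch(law$strain_model,
         blankevoort = (l * (1 + er) - lr) / lr,
         as_printed = er * l / lr)
}

#' Toe-region ligament force law
#'
#' Tension magnitude as a function of strain: zero below zero strain,
#' quadratic (`k * eps^2 / (4 * toe)`) through the toe region up to twice the
#' toe strain, and linear (`k * (eps - toe)`) beyond. The two branches and
#' their slopes agree at the transition (`k * toe` and `k`), so the law is
#' C1-continuous and non-decreasing.
#'
#' @param eps strain (dimensionless), vectorised.
#' @param stiffness_N stiffness k, N per unit strain.
#' @param law a [ligament_law()].
#' @return Force magnitude(s), N.
#' @export
strand_force_magnitude <- function(eps, stiffness_N, law = ligament_law()) {
  if (!is.numeric(stiffness_N) || stiffness_N <= 0) {
    stop("stiffness must be positive")
  }
  e1 <- law$toe_strain
  ifelse(eps < 0, 0,
         ifelse(eps <= 2 * e1,
                0.25 * stiffness_N * eps^2 / e1,
                stiffness_N * (eps - e1)))
}

#' Total ligament wrench on the tibia
#'
#' Sums the tension of every strand, applied at its tibial insertion point
#' and directed toward its femoral origin, into a single wrench about the
#' tibial origin (femoral-frame components). Slack strands contribute
#' nothing.
#'
#' @param app a referenced [ligament_apparatus()].
#' @param pose the current [rigid_pose()].
#' @return A [wrench()] in frame `"femoral"` about the tibial origin.
#' @export
apparatus_wrench <- function(app, pose) {
  stopifnot(inherits(app, "ligament_apparatus"), inherits(pose, "rigid_pose"))
  F <- c(0, 0, 0)
  M <- c(0, 0, 0)
  for (s in app$strands) {
    p_ins <- as.numeric(pose$rotation %*% s$insertion_mm) + pose$translation
    d <- s$origin_mm - p_ins
    l <- norm3(d)
    eps <- strand_strain(s, pose, app$law)
    f <- strand_force_magnitude(eps, s$stiffness_N, app$law)
    if (f > 0 && l > 0) {
      Fv <- f * d / l
      F <- F + Fv
      M <- M + cross3(p_ins - pose$translation, Fv) / 1000
    }
  }
  wrench(force_N = F, moment_Nm = M, frame_id = "femoral",
         origin_mm = pose$translation)
}

#' Remove a ligament group (e.g. PCL resection)
#'
#' @param app a [ligament_apparatus()].
#' @param group the group to resect.
#' @return A new apparatus without the group's strands; the input is
#'   unmodified.
#' @export
resect_group <- function(app, group) {
  stopifnot(inherits(app, "ligament_apparatus"))
  groups <- vapply(app$strands, `[[`, character(1), "group")
  if (!group %in% groups) {
    stop(sprintf("group '%s' not present in the apparatus (has: %s)",
                 group, paste(unique(groups), collapse = ", ")))
  }
  app$strands <- app$strands[groups != group]
  app
}

#' Scale the stiffness of one ligament group
#'
#' Multiplies the stiffness of every strand in a group by a factor (e.g. 2
#' to model intraoperative stiffening of the medial or lateral structures);
#' attachment points and reference strains are untouched.
#'
#' @param app a [ligament_apparatus()].
#' @param group the group to scale.
#' @param factor positive multiplier.
#' @return A new apparatus; the input is unmodified.
#' @export
scale_group_stiffness <- function(app, group, factor) {
  stopifnot(inherits(app, "ligament_apparatus"))
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  groups <- vapply(app$strands, `[[`, character(1), "group")
  if (!group %in% groups) {
    stop(sprintf("group '%s' not present in the apparatus (has: %s)",
                 group, paste(unique(groups), collapse = ", ")))
  }
  app$strands <- lapply(app$strands, function(s) {
    if (s$group == group) s$stiffness_N <- s$stiffness_N * factor
    s
  })
  app
}
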