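## The crosshair simulator: two laser emitters whose four fan planes form
## three orthogonal planes defining the simulator coordinate system (SCS).
## The top emitter sits on the vertical arm of the rack and fans out the
## sagittal and coronal planes; the side emitter on the horizontal arm fans
## the coronal and axial planes. The coronal plane is shared: the two
## crosshair centerlines are coplanar, and the whole bundle intersects in
## the SCS origin when the rig is calibrated.

## fan bookkeeping: (emitter, nominal normal axis, perturbation axis)
FAN_TABLE <- data.frame(
  fan = c("sagittal", "coronal_top", "coronal_side", "axial"),
  emitter = c("top", "top", "side", "side"),
  role = c("sagittal", "coronal", "coronal", "axial"),
  normal_axis = c(1L, 2L, 2L, 3L),
  stringsAsFactors = FALSE)

#' Build a simulator rig
#'
#' A nominal rig has its four laser fan planes spanning exactly the three
#' coordinate planes of the SCS.  A miscalibrated rig is modelled by
#' rotating each fan's normal about its emitter's boresight by a small
#' angle; the planes still contain the boresight (the fan always passes
#' through its emitter axis) but lose mutual orthogonality.
#'
#' @param perturbation numeric length-4 fan angles (radians), order
#'   (top-sagittal, top-coronal, side-coronal, side-axial); all zero gives
#'   a calibrated rig.  Angles must stay in the small-angle regime
#'   (< 0.2 rad).
#' @param pose \code{rigid_transform} SCS -> WORLD; default identity.
#' @param top_distance,side_distance emitter mounting distances from the
#'   SCS origin (mm); they do not affect the plane geometry.
#' @return object of class \code{simulator_rig} with fields
#'   \code{emitters}, \code{fans} (fan normals in SCS rows), \code{pose},
#'   \code{intrinsic_ok}, and the ground-truth \code{perturbation}.
#' @export
build_rig <- function(perturbation = c(0, 0, 0, 0), pose = NULL,
                      top_distance = 400, side_distance = 400) {
  if (is.null(pose)) pose <- rigid_transform("SCS", "WORLD")
  stopifnot(is.numeric(perturbation), length(perturbation) == 4L,
            all(abs(perturbation) < 0.2),
            inherits(pose, "rigid_transform"))
  if (!identical(pose$source, "SCS"))
    stop("rig pose must map from the SCS frame")
  emitters <- list(
    top = list(position = c(0, 0, top_distance), boresight = c(0, 0, -1)),
    side = list(position = c(side_distance, 0, 0), boresight = c(-1, 0, 0)))
  fans <- matrix(0, 4L, 3L,
                 dimnames = list(FAN_TABLE$fan, c("x", "y", "z")))
  for (k in seq_len(4L)) {
    nominal <- diag(3)[FAN_TABLE$normal_axis[k], ]
    bs <- emitters[[FAN_TABLE$emitter[k]]]$boresight
    Rp <- rotvec_to_matrix(bs * perturbation[k])
    fans[k, ] <- as.vector(Rp %*% nominal)
  }
  structure(list(emitters = emitters, fans = fans, pose = pose,
                 intrinsic_ok = all(perturbation == 0),
                 perturbation = perturbation),
            class = "simulator_rig")
}

#' @export
print.simulator_rig <- function(x, ...) {
  cat(sprintf("simulator_rig (%s), max orthogonality deviation %.4g deg\n",
              if (x$intrinsic_ok) "calibrated" else "perturbed",
              rig_orthogonality_deviation(x) * 180 / pi))
  invisible(x)
}

#' Set the pose of a rig
#' @param rig a \code{simulator_rig}.
#' @param pose \code{rigid_transform} SCS -> WORLD.
#' @return the rig with updated pose.
#' @export
set_rig_pose <- function(rig, pose) {
  stopifnot(inherits(rig, "simulator_rig"), inherits(pose, "rigid_transform"))
  if (!identical(pose$source, "SCS") || !identical(pose$target, "WORLD"))
    stop("rig pose must be SCS -> WORLD")
  rig$pose <- pose
  rig
}

#' Maximal deviation of the fan planes from mutual orthogonality
#'
#' Computed over all fan pairs expected orthogonal (same-role fans are
#' expected parallel and contribute their plane angle instead).
#'
#' @param rig a \code{simulator_rig}.
#' @return angle in radians.
#' @export
rig_orthogonality_deviation <- function(rig) {
  dev <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- abs(sum(rig$fans[i, ] * rig$fans[j, ]))
    ang <- acos(pmin(1, pmax(-1, ct)))  # in [0, pi/2]
    dev <- max(dev, if (FAN_TABLE$role[i] == FAN_TABLE$role[j])
      ang else abs(pi / 2 - ang))
  }
  dev
}

## Distinct fan planes with role labels; a calibrated rig collapses the two
## coronal fans into one stored plane.
rig_distinct_fans <- function(rig) {
  idx <- seq_len(4L)
  if (max(abs(rig$fans["coronal_top", ] - rig$fans["coronal_side", ])) < 1e-12)
    idx <- c(1L, 2L, 4L)
  list(normals = rig$fans[idx, , drop = FALSE],
       roles = FAN_TABLE$role[idx],
       emitters = FAN_TABLE$emitter[idx])
}

#' Project the simulator's laser crosshairs onto a surface
#'
#' Intersects the rig's (posed) laser planes with a world-frame mesh,
#' clips each curve to the side visible from its emitter, and resamples.
#' For a calibrated rig this yields three labelled curves (sagittal,
#' coronal, axial) directly comparable to scanner-marked reference lines.
#'
#' @param rig a calibrated \code{simulator_rig} with a world pose.
#' @param surface a \code{surface_mesh} in world coordinates.
#' @param step_mm resampling step (mm).
#' @param resample logical; \code{FALSE} keeps the raw intersection
#'   polylines (used internally by the deployment optimizer).
#' @return a \code{crosshair_curves}; labels whose plane misses the surface
#'   are flagged empty.
#' @export
project_crosshair <- function(rig, surface, step_mm = 0.5, resample = TRUE) {
  stopifnot(inherits(rig, "simulator_rig"), inherits(surface, "surface_mesh"))
  if (!rig$intrinsic_ok)
    stop("project_crosshair() expects a calibrated rig; run ",
         "intrinsic_calibrate() first")
  project_planes_on_mesh(surface, rig$pose, step_mm,
                         emitters = lapply(rig$emitters, `[[`, "position"),
                         resample = resample)
}

#' Projection-distortion sensitivity to surface curvature
#'
#' For each apex curvature radius, builds a paraboloid test surface, projects
#' the calibrated crosshair from a nominal pose (SCS origin at the apex) and
#' from a pose tilted by a small angle about an in-plane axis, and reports
#' the misfit between the two projections.  On flatter surfaces (larger
#' radius) the same tilt distorts the projected cross less, so misfit
#' decreases with radius: the low-curvature-radius regions of a face are
#' the ones that pin down the simulator pose.
#'
#' @param radii curvature radii to test (mm).
#' @param tilt tilt angle (radians), small-angle regime.
#' @param aperture paraboloid aperture (mm), default 80.
#' @param step_mm curve sampling step.
#' @return data.frame with columns \code{radius_mm} and \code{misfit_mm}.
#' @export
curvature_sensitivity <- function(radii, tilt, aperture = 80, step_mm = 0.5) {
  stopifnot(all(radii > 0), abs(tilt) < 0.2)
  labels <- c("sagittal", "coronal")
  mis <- vapply(radii, function(rho) {
    mesh <- make_parabolic_surface(rho, aperture)
    rig0 <- build_rig(pose = rigid_transform("SCS", "WORLD"))
    ## tilt about the axis (1,1,0)/sqrt(2) so both vertical planes distort
    ax <- c(1, 1, 0) / sqrt(2)
    rig1 <- build_rig(pose = rigid_transform("SCS", "WORLD",
                                             rotation = ax * tilt))
    c0 <- project_crosshair(rig0, mesh, step_mm)
    c1 <- project_crosshair(rig1, mesh, step_mm)
    curve_misfit(c0, c1, labels = labels)
  }, 0)
  data.frame(radius_mm = radii, misfit_mm = mis)
}

## --- rig JSON serialization -------------------------------------------------

#' Serialize a rig to JSON
#' @param rig a \code{simulator_rig}.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
rig_to_json <- function(rig, path = NULL) {
  obj <- list(perturbation = rig$perturbation,
              top_distance = rig$emitters$top$position[3],
              side_distance = rig$emitters$side$position[1],
              pose = list(source = rig$pose$source, target = rig$pose$target,
                          matrix = as.vector(t(rig$pose$matrix))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a rig from JSON
#' @param x JSON string or file path written by \code{\link{rig_to_json}}.
#' @return a \code{simulator_rig}.
#' @export
rig_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  M <- matrix(obj$pose$matrix, 4, 4, byrow = TRUE)
  pose <- rigid_transform(obj$pose$source, obj$pose$target,
                          rotation = M[1:3, 1:3], translation = M[1:3, 4])
  build_rig(perturbation = obj$perturbation, pose = pose,
            top_distance = obj$top_distance, side_distance = obj$side_distance)
}
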