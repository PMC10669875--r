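## Calibration-sphere geometry and the intrinsic / extrinsic calibration
## procedures. The sphere carries three great-circle arcs (GCA) on mutually
## orthogonal sections through its centre and three small-circle arcs (SCA)
## on parallel sections at a common offset; at offset R/sqrt(2) the three
## small circles are pairwise tangent on the sphere. Any per-role choice of
## great or small section gives three mutually orthogonal planes, so there
## are eight orthogonal combinations: one primary calibration position
## (all great) and seven secondary positions.

SPHERE_ROLES <- c("sagittal", "coronal", "axial")
SPHERE_COLOURS <- c(sagittal = "red", coronal = "blue", axial = "black")

#' Build a calibration sphere
#'
#' @param radius sphere radius (mm), default 60.
#' @param centre sphere centre (mm), default origin.
#' @param sca_offset offset of the small-circle sections from the centre;
#'   default \code{radius / sqrt(2)}, the value at which the three small
#'   circles are pairwise tangent on the sphere surface.
#' @return object of class \code{calibration_sphere} with fields
#'   \code{radius}, \code{centre}, \code{gca_normals} (3 x 3, rows keyed by
#'   role), \code{sca_normals} (identical by construction), and
#'   \code{sca_offset}.
#' @export
build_calibration_sphere <- function(radius = 60, centre = c(0, 0, 0),
                                     sca_offset = radius / sqrt(2)) {
  stopifnot(is.numeric(radius), radius > 0, length(centre) == 3L,
            sca_offset > 0, sca_offset < radius)
  N <- diag(3)
  dimnames(N) <- list(SPHERE_ROLES, c("x", "y", "z"))
  structure(list(radius = radius, centre = as.numeric(centre),
                 gca_normals = N, sca_normals = N, sca_offset = sca_offset,
                 colours = SPHERE_COLOURS),
            class = "calibration_sphere")
}

#' @export
print.calibration_sphere <- function(x, ...) {
  cat(sprintf(
    "calibration_sphere: R = %g mm, small-circle offset = %.4f mm\n",
    x$radius, x$sca_offset))
  invisible(x)
}

#' Count intersection points of two orthogonal small circles on the sphere
#'
#' The small circles on two orthogonal sections at offset \code{d} meet on
#' the sphere where both plane constraints and the sphere equation hold;
#' the count is found numerically by dense sampling of one circle and
#' root-clustering of its distance to the other.  Two points for
#' \code{d < R/sqrt(2)}, one (tangency) at \code{d = R/sqrt(2)}, none
#' beyond.
#'
#' @param s a \code{calibration_sphere}.
#' @param d section offset (mm); defaults to the sphere's own.
#' @param n number of samples along the probing circle.
#' @param tol distance below which a sample counts as an intersection.
#' @return integer intersection count.
#' @export
small_circle_intersection_count <- function(s, d = s$sca_offset, n = 20000,
                                            tol = 0.02) {
  stopifnot(inherits(s, "calibration_sphere"), d > 0)
  R <- s$radius
  if (d >= R) return(0L)
  r <- sqrt(R^2 - d^2)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ## circle 1: plane x = d (local frame); circle 2: plane y = d
  P <- cbind(d, r * cos(th), r * sin(th))
  dist2 <- point_to_circle_distance(P, centre = c(0, d, 0),
                                    normal = c(0, 1, 0), radius = r)
  ## count near-zero local minima of the sampled distance (circular),
  ## merging minima that touch: transversal crossings give one each,
  ## a tangency gives a single flat minimum
  lo <- c(n, seq_len(n - 1L)); hi <- c(seq_len(n)[-1L], 1L)
  is_min <- dist2 <= dist2[lo] & dist2 <= dist2[hi] & dist2 < tol
  if (!any(is_min)) return(0L)
  runs <- rle(as.vector(is_min))
  cnt <- sum(runs$values)
  if (is_min[1L] && is_min[n] && cnt > 1L) cnt <- cnt - 1L
  as.integer(cnt)
}

## distance from points to a circle in 3D (centre c, unit normal n, radius r)
point_to_circle_distance <- function(P, centre, normal, radius) {
  if (is.null(dim(P))) P <- matrix(P, 1L, 3L)
  Q <- sweep(P, 2L, centre)
  h <- as.vector(Q %*% normal)
  inplane <- Q - outer(h, normal)
  rho <- sqrt(rowSums(inplane^2))
  sqrt((rho - radius)^2 + h^2)
}

#' Enumerate the orthogonal arc-plane combinations of a calibration sphere
#'
#' Tries all per-role choices of great or small section and keeps those
#' whose three plane normals are mutually orthogonal within \code{tol}.
#' For a nominal sphere all 8 combinations qualify: the all-great primary
#' calibration position (PCP) and 7 secondary positions (SCP) containing
#' at least one small circle.
#'
#' @param s a \code{calibration_sphere}.
#' @param tol orthogonality tolerance (radians on the angle between plane
#'   normals' deviation from 90 degrees).
#' @return data.frame with one row per qualifying combination: per-role
#'   selector columns (\code{"great"}/\code{"small"}) and a \code{label}
#'   column (\code{"PCP"} or \code{"SCP1"}..).
#' @export
enumerate_orthogonal_combinations <- function(s, tol = 1e-6) {
  stopifnot(inherits(s, "calibration_sphere"))
  grid <- expand.grid(sagittal = c("great", "small"),
                      coronal = c("great", "small"),
                      axial = c("great", "small"),
                      stringsAsFactors = FALSE)
  ok <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    N <- t(vapply(SPHERE_ROLES, function(role)
      if (grid[k, role] == "great") s$gca_normals[role, ]
      else s$sca_normals[role, ], numeric(3)))
    dots <- abs(c(sum(N[1, ] * N[2, ]), sum(N[1, ] * N[3, ]),
                  sum(N[2, ] * N[3, ])))
    ok[k] <- all(asin(pmin(1, dots)) <= tol)
  }
  out <- grid[ok, , drop = FALSE]
  is_pcp <- apply(out == "great", 1L, all)
  out$label <- NA_character_
  out$label[is_pcp] <- "PCP"
  out$label[!is_pcp] <- paste0("SCP", seq_len(sum(!is_pcp)))
  rownames(out) <- NULL
  out
}

#' The primary calibration position of a sphere
#' @param s a \code{calibration_sphere}.
#' @return the all-great row of
#'   \code{\link{enumerate_orthogonal_combinations}}.
#' @export
primary_calibration_position <- function(s) {
  combos <- enumerate_orthogonal_combinations(s)
  combos[combos$label == "PCP", , drop = FALSE]
}

## Sphere placement for a calibration position: the sphere is moved so the
## three selected sections coincide with the rig's three laser planes,
## i.e. all pass through the SCS origin. Returns the centre (SCS frame)
## and per-role marked-circle descriptions.
position_placement <- function(s, pos) {
  sel <- vapply(SPHERE_ROLES, function(role) pos[[role]][1L], "")
  offs <- ifelse(sel == "small", s$sca_offset, 0)
  centre <- -as.vector(t(s$gca_normals) %*% offs)
  circles <- lapply(seq_along(SPHERE_ROLES), function(i) {
    n <- s$gca_normals[i, ]
    list(centre = centre + offs[i] * n, normal = n,
         radius = sqrt(s$radius^2 - offs[i]^2))
  })
  names(circles) <- SPHERE_ROLES
  list(centre = centre, circles = circles)
}

#' Residual between projected and marked arcs at a calibration position
#'
#' The sphere is held at the given calibration position (its selected
#' sections coinciding with the nominal laser planes).  Each of the rig's
#' four fan planes is intersected with the sphere, the resulting projected
#' circle is sampled, and the mean distance to the same-role marked circle
#' is taken; the residual is the mean over fans.  Zero for a calibrated
#' rig at any of the eight positions.
#'
#' @param rig a \code{simulator_rig} (pose ignored; computed in SCS).
#' @param s a \code{calibration_sphere}.
#' @param pos one row of \code{\link{enumerate_orthogonal_combinations}}
#'   (defaults to the PCP).
#' @param n_samples samples per projected circle.
#' @return mean residual (mm).
#' @export
arc_residual <- function(rig, s, pos = NULL, n_samples = 200) {
  stopifnot(inherits(rig, "simulator_rig"), inherits(s, "calibration_sphere"))
  if (is.null(pos)) pos <- primary_calibration_position(s)
  pl <- position_placement(s, pos)
  total <- 0
  for (k in seq_len(4L)) {
    n <- rig$fans[k, ]
    role <- FAN_TABLE$role[k]
    ## fan plane passes through the SCS origin (it contains the emitter axis)
    h <- sum(n * pl$centre)
    if (abs(h) >= s$radius)
      stop("fan '", FAN_TABLE$fan[k], "' misses the calibration sphere")
    foot <- pl$centre - h * n
    r_p <- sqrt(s$radius^2 - h^2)
    ## orthonormal basis of the fan plane
    u <- pick_orthogonal(n)
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    th <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
    P <- sweep(outer(cos(th), u) * r_p + outer(sin(th), v) * r_p, 2L,
               foot, "+")
    mk <- pl$circles[[role]]
    total <- total + mean(point_to_circle_distance(P, mk$centre, mk$normal,
                                                   mk$radius))
  }
  total / 4
}

pick_orthogonal <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u / sqrt(sum(u^2))
}

#' Intrinsic calibration of a perturbed rig
#'
#' Recovers the four fan-normal angles by minimizing the arc residual at
#' the primary calibration position with a derivative-free simplex search
#' (plus a per-angle line-search polish), then verifies the result at all
#' eight positions, mirroring the physical procedure of adjusting the laser
#' screws at the PCP and checking the seven SCPs.
#'
#' @param rig a (possibly perturbed) \code{simulator_rig}.
#' @param s a \code{calibration_sphere}.
#' @param max_residual_mm verification threshold; exceeding it at any
#'   position raises a non-convergence error.
#' @param n_samples samples per projected circle in the residual.
#' @return list with the calibrated \code{rig} and a \code{report} holding
#'   per-position before/after residuals, the recovered correction angles
#'   and the ground-truth perturbation.
#' @export
intrinsic_calibrate <- function(rig, s, max_residual_mm = 0.01,
                                n_samples = 200) {
  stopifnot(inherits(rig, "simulator_rig"), inherits(s, "calibration_sphere"),
            all(abs(rig$perturbation) <= 5 * pi / 180 + 1e-12))
  combos <- enumerate_orthogonal_combinations(s)
  pcp <- combos[combos$label == "PCP", , drop = FALSE]
  rig_with <- function(corr)
    build_rig(perturbation = rig$perturbation + corr, pose = rig$pose,
              top_distance = rig$emitters$top$position[3],
              side_distance = rig$emitters$side$position[1])
  obj <- function(corr) arc_residual(rig_with(corr), s, pcp, n_samples)
  before <- vapply(seq_len(nrow(combos)), function(k)
    arc_residual(rig, s, combos[k, , drop = FALSE], n_samples), 0)
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  corr <- fit$par
  ## per-angle polish: the four angles decouple in the PCP residual, so a
  ## couple of coordinate line-search sweeps finish the simplex solution
  for (sweep_k in 1:2) for (i in 1:4) {
    f1 <- function(a) { cc <- corr; cc[i] <- a; obj(cc) }
    op <- stats::optimize(f1, c(corr[i] - 0.03, corr[i] + 0.03),
                          tol = 1e-12)
    corr[i] <- op$minimum
  }
  calibrated <- rig_with(corr)
  calibrated$intrinsic_ok <- TRUE
  calibrated$perturbation <- c(0, 0, 0, 0)
  after <- vapply(seq_len(nrow(combos)), function(k)
    arc_residual(calibrated, s, combos[k, , drop = FALSE], n_samples), 0)
  if (max(after) > max_residual_mm)
    stop(sprintf(paste0("intrinsic calibration failed to converge: max ",
                        "residual %.4g mm over the calibration positions"),
                 max(after)))
  list(rig = calibrated,
       report = list(positions = combos$label, before = before,
                     after = after, recovered_correction = corr,
                     true_perturbation = rig$perturbation,
                     recovery_error_rad = max(abs(corr + rig$perturbation))))
}

#' Extrinsic calibration: recover the virtual-to-reference transform
#'
#' Simulates aligning the virtual calibration sphere with the physical one
#' held at the primary calibration position.  The physical sphere's three
#' great circles live in the reference image frame (RICS); their observed
#' counterparts, expressed in the virtual frame (VCS) through the unknown
#' true transform, are sampled (optionally with isotropic noise) and the
#' candidate VCS-to-RICS transform is fitted by Levenberg-Marquardt least
#' squares on point-to-circle distances.
#'
#' @param initial \code{rigid_transform} VCS -> RICS starting guess,
#'   within roughly (20 mm, 15 deg) of the truth.
#' @param s a \code{calibration_sphere} (the physical sphere at the PCP,
#'   centred at the RICS origin).
#' @param truth the ground-truth VCS -> RICS transform used to synthesize
#'   the observations.
#' @param noise_sigma isotropic per-point Gaussian noise on the observed
#'   circle points (mm), default 0.
#' @param n_samples sampled points per circle, default 500.
#' @param seed RNG seed for the noise draw.
#' @return list with the recovered \code{transform} and a \code{report}
#'   (rms residual, translation / rotation recovery errors).
#' @export
extrinsic_calibrate <- function(initial, s, truth, noise_sigma = 0,
                                n_samples = 500, seed = 20231107) {
  stopifnot(inherits(initial, "rigid_transform"),
            inherits(truth, "rigid_transform"),
            inherits(s, "calibration_sphere"))
  dev <- pose_difference(initial, truth)
  if (dev$translation_mm > 50 || dev$rotation_deg > 45)
    stop("initial guess is outside the calibration basin (",
         sprintf("%.1f mm, %.1f deg", dev$translation_mm, dev$rotation_deg),
         ")")
  circles <- lapply(seq_len(3L), function(i)
    list(centre = s$centre, normal = s$gca_normals[i, ], radius = s$radius))
  ## observed points: physical circles pulled into VCS through the truth
  inv_truth <- invert(truth)
  obs <- lapply(circles, function(ci) {
    u <- pick_orthogonal(ci$normal)
    v <- c(ci$normal[2] * u[3] - ci$normal[3] * u[2],
           ci$normal[3] * u[1] - ci$normal[1] * u[3],
           ci$normal[1] * u[2] - ci$normal[2] * u[1])
    th <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
    P <- sweep(outer(cos(th), u) + outer(sin(th), v), 2L, ci$centre /
               ci$radius, "+") * ci$radius
    apply_transform(inv_truth, P)
  })
  if (noise_sigma > 0) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    obs <- lapply(obs, function(P)
      P + matrix(stats::rnorm(length(P), 0, noise_sigma), nrow(P), 3L))
  }
  par0 <- c(matrix_to_rotvec(rotation_of(initial)), translation_of(initial))
  resid_fn <- function(par) {
    R <- rotvec_to_matrix(par[1:3])
    t <- par[4:6]
    unlist(lapply(seq_len(3L), function(i) {
      P <- obs[[i]] %*% t(R)
      P <- sweep(P, 2L, t, "+")
      ci <- circles[[i]]
      point_to_circle_distance(P, ci$centre, ci$normal, ci$radius)
    }))
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  recovered <- rigid_transform("VCS", "RICS",
                               rotation = rotvec_to_matrix(fit$par[1:3]),
                               translation = fit$par[4:6])
  rms <- sqrt(mean(resid_fn(fit$par)^2))
  if (noise_sigma == 0 && rms > 0.1)
    stop(sprintf("extrinsic calibration did not converge (rms %.4g mm)", rms))
  err <- pose_difference(recovered, truth)
  list(transform = recovered,
       report = list(rms_mm = rms, translation_error_mm = err$translation_mm,
                     rotation_error_deg = err$rotation_deg,
                     niter = fit$niter))
}

## save / restore the global RNG state around seeded simulations
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
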