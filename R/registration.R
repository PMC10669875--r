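## Simulator deployment (6-DOF pose recovery against the marked skin
## lines) and hologram registration with freeze/unfreeze state.

#' Deploy the simulator against marked reference lines
#'
#' Recovers the 6-DOF pose of the calibrated simulator that makes its
#' projected crosshair curves coincide with the scanner-marked lines on
#' the head surface — the algorithmic counterpart of the manual alignment
#' step.  A multi-start Nelder-Mead search over (rotation vector,
#' translation) minimizes the mean distance from marked-line points to the
#' projected curves, followed by a Levenberg-Marquardt polish on the
#' point-to-curve residual vector.  Perfect alignment means the simulator
#' reproduces the scanner frame, i.e. the SCS-to-scanner transform is the
#' identity; residual misfit is reported, never absorbed.
#'
#' @param marked \code{crosshair_curves} marked on the surface (world
#'   frame).
#' @param surface the \code{surface_mesh} in world coordinates.
#' @param rig a calibrated \code{simulator_rig}.
#' @param init \code{rigid_transform} SCS -> WORLD initial pose, within
#'   the configured basin (default 10 mm, 10 deg) of the truth.
#' @param opts list of options: \code{n_starts} (default 8 seeded simplex
#'   starts), \code{seed}, \code{accept_misfit_mm} (early-exit and success
#'   threshold, default 0.05), \code{max_points} (marked points used in the
#'   objective, default 400), \code{basin_mm}/\code{basin_deg} (jitter
#'   radius of the extra starts).
#' @return list with \code{pose} (recovered SCS -> WORLD), \code{misfit}
#'   (symmetric curve misfit at the recovered pose, mm), \code{t_ssc}
#'   (identity SCS -> SCANNER under the perfect-alignment convention) and
#'   \code{starts_used}.
#' @export
deploy_simulator <- function(marked, surface, rig, init, opts = list()) {
  stopifnot(inherits(marked, "crosshair_curves"),
            inherits(surface, "surface_mesh"),
            inherits(rig, "simulator_rig"),
            inherits(init, "rigid_transform"))
  if (!rig$intrinsic_ok) stop("deploy_simulator() requires a calibrated rig")
  o <- utils::modifyList(list(n_starts = 8L, seed = 20231107,
                              accept_misfit_mm = 0.05, max_points = 400L,
                              basin_mm = 5, basin_deg = 5,
                              max_misfit_mm = 0.5), opts)
  labels <- names(which(!marked$empty))
  if (length(labels) == 0L) stop("marked lines are empty")
  ## fixed, evenly thinned marked point set for the objective
  Pm <- curve_points(marked, labels)
  lab_of <- rep(labels, vapply(labels, function(lb)
    nrow(curve_points(marked, lb)), 0L))
  if (nrow(Pm) > o$max_points) {
    idx <- unique(round(seq(1L, nrow(Pm), length.out = o$max_points)))
    Pm <- Pm[idx, , drop = FALSE]
    lab_thin <- lab_of[idx]
  } else lab_thin <- lab_of

  pose_from_par <- function(par)
    rigid_transform("SCS", "WORLD", rotation = rotvec_to_matrix(par[1:3]),
                    translation = par[4:6])
  residuals_at <- function(par) {
    pose <- pose_from_par(par)
    pc <- project_crosshair(set_rig_pose(rig, pose), surface,
                            step_mm = marked$step, resample = FALSE)
    out <- rep(50, nrow(Pm))  # penalty for points with no curve to match
    for (lb in labels) {
      idx <- lab_thin == lb
      segs <- components_segments(pc$curves[[lb]])
      if (is.null(segs)) next
      out[idx] <- points_to_segments_distance(Pm[idx, , drop = FALSE], segs)
    }
    out
  }
  obj <- function(par) mean(residuals_at(par))

  par_init <- c(matrix_to_rotvec(rotation_of(init)), translation_of(init))
  old <- set_local_seed(o$seed)
  on.exit(restore_seed(old), add = TRUE)
  starts <- list(par_init)
  for (k in seq_len(o$n_starts - 1L)) {
    jit_r <- stats::rnorm(3, 0, o$basin_deg * pi / 180 / 2)
    jit_t <- stats::rnorm(3, 0, o$basin_mm / 2)
    starts[[k + 1L]] <- par_init + c(jit_r, jit_t)
  }
  best <- NULL
  used <- 0L
  for (st in starts) {
    used <- used + 1L
    nm <- stats::optim(st, obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    lm <- minpack.lm::nls.lm(nm$par, fn = residuals_at,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 100, ftol = 1e-15, ptol = 1e-12))
    val <- mean(residuals_at(lm$par))
    if (is.null(best) || val < best$val) best <- list(par = lm$par, val = val)
    if (best$val < o$accept_misfit_mm) break
  }
  pose <- pose_from_par(best$par)
  final <- project_crosshair(set_rig_pose(rig, pose), surface,
                             step_mm = marked$step)
  mis <- curve_misfit(final, marked, labels = labels)
  if (mis > o$max_misfit_mm)
    stop(sprintf(paste0("deployment failure: best misfit %.3f mm over %d ",
                        "start(s) exceeds %.3f mm"), mis, used,
                 o$max_misfit_mm))
  list(pose = pose, misfit = mis,
       t_ssc = rigid_transform("SCS", "SCANNER"), starts_used = used)
}

#' Finite-difference information matrix of the deployment objective
#'
#' Gauss-Newton approximation J'J of the squared point-to-curve misfit at
#' a pose, by central finite differences of the residual vector along the
#' six pose parameters (rotation vector then translation).  Its rank
#' reveals which degrees of freedom the visible crosshair projection
#' constrains: a single crosshair on a flat plate leaves the emitter
#' boresight translation unconstrained, while a generically curved surface
#' pins all six.
#'
#' @param marked \code{crosshair_curves} to match.
#' @param surface the \code{surface_mesh}.
#' @param rig a calibrated \code{simulator_rig}.
#' @param pose the pose at which to differentiate (truth, typically).
#' @param labels curve labels to use (defaults to non-empty ones).
#' @param h finite-difference step (radians / mm).
#' @return 6 x 6 information matrix.
#' @export
deployment_information <- function(marked, surface, rig, pose,
                                   labels = NULL, h = 1e-3) {
  if (is.null(labels)) labels <- names(which(!marked$empty))
  Pm <- curve_points(marked, labels)
  lab_of <- rep(labels, vapply(labels, function(lb)
    nrow(curve_points(marked, lb)), 0L))
  res <- function(par) {
    p <- rigid_transform("SCS", "WORLD",
                         rotation = rotvec_to_matrix(par[1:3]),
                         translation = par[4:6])
    pc <- project_crosshair(set_rig_pose(rig, p), surface,
                            step_mm = marked$step, resample = FALSE)
    out <- rep(50, nrow(Pm))
    for (lb in labels) {
      segs <- components_segments(pc$curves[[lb]])
      if (is.null(segs)) next
      out[lab_of == lb] <-
        points_to_segments_distance(Pm[lab_of == lb, , drop = FALSE], segs)
    }
    out
  }
  par0 <- c(matrix_to_rotvec(rotation_of(pose)), translation_of(pose))
  ## forward differences from the base pose: at the true pose the
  ## residuals are unsigned distances at their minimum, so one-sided
  ## differences measure constraint strength where central ones cancel
  r0 <- res(par0)
  J <- matrix(0, length(r0), 6L)
  for (i in 1:6) {
    pp <- par0; pp[i] <- pp[i] + h
    J[, i] <- (res(pp) - r0) / h
  }
  crossprod(J)
}

#' Map hologram model points through the registration chain
#'
#' Resolves the world-to-scanner transform from the frame graph and maps
#' model points given in the reference image frame into world coordinates
#' (the scanner and reference image frames coincide once the simulator is
#' deployed).  With all-true transforms the mapped fiducials coincide with
#' their physical counterparts.
#'
#' @param graph a \code{frame_graph} containing the five chain transforms.
#' @param model_points n x 3 matrix of points in the RICS frame (mm).
#' @return n x 3 matrix of points in the WORLD frame.
#' @export
register_holograms <- function(graph, model_points) {
  T_WSc <- chain_world_to_scanner(graph)
  apply_transform(invert(T_WSc), model_points)
}

## --- freeze / unfreeze state ------------------------------------------------

#' Create a registration state
#'
#' Models the hold-vs-track toggle of the hologram registration: in LIVE
#' mode the reported transform tracks the live source; FREEZE snapshots it
#' to a spatial anchor.  An optional drift model (isotropic Gaussian
#' random walk on translation, seeded) emulates the slow anchor drift of
#' inside-out tracking; unfreezing discards accumulated drift, the
#' loop-closure analogue.
#'
#' @param live \code{rigid_transform}, the live registration transform.
#' @param drift_sigma per-axis random-walk step (mm); 0 disables drift.
#' @param seed RNG seed for the drift walk.
#' @return object of class \code{registration_state} in LIVE mode.
#' @export
registration_state <- function(live, drift_sigma = 0, seed = 20231107) {
  stopifnot(inherits(live, "rigid_transform"), drift_sigma >= 0)
  structure(list(mode = "LIVE", live = live, anchor = NULL,
                 drift = c(0, 0, 0), drift_sigma = drift_sigma,
                 seed = seed, steps = 0L),
            class = "registration_state")
}

#' Freeze the registration
#' @param state a \code{registration_state}.
#' @return the state in FROZEN mode, anchored at the current transform.
#' @export
freeze <- function(state) {
  stopifnot(inherits(state, "registration_state"))
  state$mode <- "FROZEN"
  state$anchor <- state$live
  state$drift <- c(0, 0, 0)
  state$steps <- 0L
  state
}

#' Unfreeze the registration
#'
#' Restores live tracking; any accumulated anchor drift is discarded.
#' @param state a \code{registration_state}.
#' @return the state in LIVE mode.
#' @export
unfreeze <- function(state) {
  stopifnot(inherits(state, "registration_state"))
  state$mode <- "LIVE"
  state$anchor <- NULL
  state$drift <- c(0, 0, 0)
  state$steps <- 0L
  state
}

#' Advance the drift model by n steps
#'
#' Only meaningful in FROZEN mode with a nonzero drift sigma; each step
#' adds an independent N(0, sigma^2) increment per translation axis.
#'
#' @param state a \code{registration_state}.
#' @param n number of steps.
#' @return the updated state.
#' @export
step_drift <- function(state, n = 1L) {
  stopifnot(inherits(state, "registration_state"))
  if (state$mode != "FROZEN" || state$drift_sigma == 0 || n < 1L)
    return(state)
  old <- set_local_seed(state$seed + state$steps)
  on.exit(restore_seed(old), add = TRUE)
  inc <- matrix(stats::rnorm(3L * n, 0, state$drift_sigma), n, 3L)
  state$drift <- state$drift + colSums(inc)
  state$steps <- state$steps + as.integer(n)
  state
}

#' Current reported transform of a registration state
#' @param state a \code{registration_state}.
#' @return a \code{rigid_transform}: the live transform in LIVE mode, the
#'   anchored snapshot (plus any drift) in FROZEN mode.
#' @export
current_transform <- function(state) {
  stopifnot(inherits(state, "registration_state"))
  if (state$mode == "LIVE") return(state$live)
  T <- state$anchor
  rigid_transform(T$source, T$target, rotation = rotation_of(T),
                  translation = translation_of(T) + state$drift)
}
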