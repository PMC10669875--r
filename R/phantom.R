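## Seeded generators of head-like surfaces, paraboloid test patches,
## fiducials, scanner poses and complete registration fixtures, so every
## pipeline stage is exercisable without any imaging download.

#' Generate a synthetic head-like surface mesh
#'
#' A superellipsoid (p-norm ball, exponent ~2.5) with half-axes roughly
#' those of an adult head, plus a protruding paraboloid-like nasal bump —
#' the low-curvature-radius feature that makes crosshair projections
#' informative.  Axes follow LPS (x left, y posterior, z superior), so the
#' nose points along -y.  Deterministic per (params, seed); the seed
#' drives a mild random axis asymmetry.
#'
#' @param size overall scale factor, default 1 (half-axes 75/95/115 mm).
#' @param asymmetry sd of the per-axis log-scale jitter, default 0.02.
#' @param nose_prominence nasal bump height (mm), default 22.
#' @param n_theta,n_phi azimuthal / latitudinal resolution.
#' @param exponent superellipsoid exponent, default 2.5.
#' @param seed RNG seed.
#' @return a watertight \code{surface_mesh} with outward normals.
#' @export
make_head_mesh <- function(size = 1, asymmetry = 0.02, nose_prominence = 22,
                           n_theta = 48L, n_phi = 36L, exponent = 2.5,
                           seed = 20231107) {
  stopifnot(size > 0, nose_prominence >= 0, n_theta >= 8L, n_phi >= 6L)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ax <- c(75, 95, 115) * size * exp(stats::rnorm(3L, 0, asymmetry))
  ## lat/lon grid of directions, poles handled separately
  phi <- seq(-pi / 2, pi / 2, length.out = n_phi + 2L)[-c(1L, n_phi + 2L)]
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  dirs <- cbind(rep(cos(phi), each = n_theta) * cos(theta),
                rep(cos(phi), each = n_theta) * sin(theta),
                rep(sin(phi), each = n_theta))
  dirs <- rbind(dirs, c(0, 0, -1), c(0, 0, 1))
  r <- (abs(dirs[, 1] / ax[1])^exponent + abs(dirs[, 2] / ax[2])^exponent +
          abs(dirs[, 3] / ax[3])^exponent)^(-1 / exponent)
  V <- dirs * r
  ## nasal bump: radial displacement peaked around the anterior direction
  d0 <- c(0, -1, -0.25); d0 <- d0 / sqrt(sum(d0^2))
  ca <- pmin(1, pmax(-1, dirs %*% d0))
  ang <- acos(ca)
  V <- V + dirs * as.vector(nose_prominence * exp(-(ang / 0.22)^2 / 2))
  ## faces: grid quads split into triangles, plus pole fans
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  F <- list()
  for (i in seq_len(n_phi - 1L)) {
    j <- seq_len(n_theta)
    a <- idx(i, j); b <- idx(i, j + 1L)
    c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    F[[length(F) + 1L]] <- cbind(a, b, d)
    F[[length(F) + 1L]] <- cbind(a, d, c)
  }
  south <- nrow(V) - 1L; north <- nrow(V)
  j <- seq_len(n_theta)
  F[[length(F) + 1L]] <- cbind(south, idx(1L, j + 1L), idx(1L, j))
  F[[length(F) + 1L]] <- cbind(north, idx(n_phi, j), idx(n_phi, j + 1L))
  mesh <- surface_mesh(V, do.call(rbind, F))
  orient_outward(mesh)
}

## flip all faces if the signed volume is negative (inward orientation)
orient_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  vol <- sum(rowSums(a * cross3(b, c))) / 6
  if (vol < 0) mesh <- surface_mesh(V, F[, c(1L, 3L, 2L)])
  mesh
}

#' Generate an open paraboloid test surface
#'
#' z = (x^2 + y^2) / (2 rho) over a circular aperture: apex at the origin,
#' apex curvature radius equal to \code{curvature_radius}, normals facing
#' up toward the emitters.  The standard bench surface for the
#' projection-distortion experiment.
#'
#' @param curvature_radius apex curvature radius rho (mm).
#' @param aperture aperture diameter (mm), default 80.
#' @param n_r,n_theta radial / angular resolution.
#' @return an open \code{surface_mesh}.
#' @export
make_parabolic_surface <- function(curvature_radius, aperture = 80,
                                   n_r = 28L, n_theta = 56L) {
  stopifnot(curvature_radius > 0, aperture > 0)
  rr <- seq(0, aperture / 2, length.out = n_r + 1L)[-1L]
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  x <- as.vector(outer(cos(th), rr))
  y <- as.vector(outer(sin(th), rr))
  V <- cbind(x, y, (x^2 + y^2) / (2 * curvature_radius))
  V <- rbind(c(0, 0, 0), V)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  F <- list()
  j <- seq_len(n_theta)
  F[[1L]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  for (i in seq_len(n_r - 1L)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    F[[length(F) + 1L]] <- cbind(a, d, b)
    F[[length(F) + 1L]] <- cbind(a, c, d)
  }
  mesh <- surface_mesh(V, do.call(rbind, F))
  ## orient normals upward (+z side, toward the top emitter)
  if (mean(mesh$normals[, 3]) < 0)
    mesh <- surface_mesh(V, mesh$faces[, c(1L, 3L, 2L)])
  mesh
}

#' Place fiducial markers on a mesh surface
#'
#' Picks n well-separated scalp vertices (upper half of the mesh) by
#' seeded rejection sampling with a minimum pairwise distance, labelled
#' A..; the markers are measurement-only points, never used to register.
#'
#' @param mesh a \code{surface_mesh}.
#' @param n number of markers, default 6 (labels A-F).
#' @param min_separation minimum pairwise Euclidean distance (mm).
#' @param seed RNG seed.
#' @param max_tries rejection retry cap.
#' @return a \code{fiducial_set} in the WORLD frame.
#' @export
place_fiducials <- function(mesh, n = 6L, min_separation = 50,
                            seed = 20231107, max_tries = 2000L) {
  stopifnot(inherits(mesh, "surface_mesh"), n >= 3L)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  V <- mesh$vertices
  cand <- which(V[, 3] > stats::quantile(V[, 3], 0.45))
  picked <- integer(0)
  tries <- 0L
  while (length(picked) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n, " fiducials with separation ",
           min_separation, " mm after ", max_tries, " tries")
    cand_i <- sample(cand, 1L)
    if (length(picked) == 0L ||
        min(sqrt(rowSums((V[picked, , drop = FALSE] -
          matrix(V[cand_i, ], length(picked), 3L, byrow = TRUE))^2))) >=
        min_separation)
      picked <- c(picked, cand_i)
  }
  fiducial_set(V[picked, , drop = FALSE], LETTERS[seq_len(n)],
               frame = "WORLD")
}

#' Write a fiducial set to CSV
#' @param fid a \code{fiducial_set}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
fiducials_to_csv <- function(fid, path) {
  utils::write.csv(data.frame(label = fid$labels, x = fid$points[, 1],
                              y = fid$points[, 2], z = fid$points[, 3],
                              frame = fid$frame), path, row.names = FALSE)
  invisible(path)
}

#' Read a fiducial set from CSV
#' @param path CSV written by \code{\link{fiducials_to_csv}}.
#' @return a \code{fiducial_set}.
#' @export
fiducials_from_csv <- function(path) {
  df <- utils::read.csv(path)
  fiducial_set(as.matrix(df[, c("x", "y", "z")]), df$label,
               frame = df$frame[1])
}

#' Build a complete, internally consistent phantom fixture
#'
#' Assembles a synthetic head mesh, six scalp fiducials, a seeded scanner
#' pose (reference image origin near the head centroid with a mild
#' orientation perturbation), the scanner-marked reference lines on the
#' surface, the scan geometry of the reference image, and a consistent
#' frame graph (world/HMD/virtual-frame transforms drawn at random, the
#' extrinsic transform solved so the chain closes exactly).  Running
#' deployment, hologram registration and the measurement protocol on the
#' fixture with zero noise yields TRE below 1e-6 mm by construction.
#'
#' @param config optional list overriding defaults: \code{step_mm},
#'   \code{head} (params passed to \code{\link{make_head_mesh}}),
#'   \code{n_fiducials}, \code{scanner_jitter_mm},
#'   \code{scanner_jitter_deg}, \code{scan_geometry}.
#' @param seed RNG seed driving every random element.
#' @return object of class \code{phantom_fixture}: list with \code{mesh},
#'   \code{fiducials} (WORLD), \code{fiducials_rics} (the reference points
#'   P in RICS), \code{scanner_pose} (RICS -> WORLD), \code{marked_lines},
#'   \code{scan_geometry}, \code{graph} (full frame graph), \code{rig}
#'   (calibrated, at identity pose) and \code{seed}.
#' @export
make_fixture <- function(config = list(), seed = 20231107) {
  cfg <- utils::modifyList(list(step_mm = 0.75, head = list(),
                                n_fiducials = 6L, scanner_jitter_mm = 8,
                                scanner_jitter_deg = 6,
                                scan_geometry = scan_geometry(
                                  c(251, 251), c(128, 128), 0.625, 256L)),
                           config)
  mesh <- do.call(make_head_mesh, c(cfg$head, list(seed = seed)))
  fid <- place_fiducials(mesh, cfg$n_fiducials, seed = seed + 1L)
  old <- set_local_seed(seed + 2L)
  on.exit(restore_seed(old), add = TRUE)
  centroid <- colMeans(mesh$vertices)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, cfg$scanner_jitter_deg * pi / 180)
  scanner_pose <- rigid_transform(
    "RICS", "WORLD", rotation = ax * ang,
    translation = centroid + stats::rnorm(3, 0, cfg$scanner_jitter_mm / 2))
  marked <- mark_reference_lines(mesh, scanner_pose, cfg$step_mm)
  ## frame graph consistent with the scanner pose: SCS coincides with the
  ## scanner frame under perfect deployment, so T_WS = inverse scanner pose
  T_WH <- random_rigid_transform("WORLD", "HMD", max_angle = pi / 2,
                                 max_translation = 500)
  T_HV <- random_rigid_transform("HMD", "VCS", max_angle = pi / 2,
                                 max_translation = 300)
  T_RS <- rigid_transform("RICS", "SCS")
  T_SSc <- rigid_transform("SCS", "SCANNER")
  M_WS <- solve(scanner_pose$matrix)        # world -> SCS (== RICS axes)
  M_WV <- T_HV$matrix %*% T_WH$matrix
  M_VR <- solve(T_RS$matrix) %*% M_WS %*% solve(M_WV)
  T_VR <- rigid_transform("VCS", "RICS", rotation = M_VR[1:3, 1:3],
                          translation = M_VR[1:3, 4])
  graph <- frame_graph(T_WH, T_HV, T_VR, T_RS, T_SSc)
  fid_rics <- fiducial_set(apply_transform(invert(scanner_pose),
                                           fid$points),
                           fid$labels, frame = "RICS")
  structure(list(mesh = mesh, fiducials = fid, fiducials_rics = fid_rics,
                 scanner_pose = scanner_pose, marked_lines = marked,
                 scan_geometry = cfg$scan_geometry, graph = graph,
                 rig = build_rig(), seed = seed, step_mm = cfg$step_mm),
            class = "phantom_fixture")
}

#' @export
print.phantom_fixture <- function(x, ...) {
  cat(sprintf(paste0("phantom_fixture (seed %d): %d-vertex head, %d ",
                     "fiducials, marked lines in %d label(s)\n"),
              x$seed, nrow(x$mesh$vertices), length(x$fiducials$labels),
              sum(!x$marked_lines$empty)))
  invisible(x)
}
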