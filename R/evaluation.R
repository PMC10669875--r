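## TRE measurement protocol, least-squares error extrapolation,
## model-to-model distance maps and summary statistics.

#' Construct a fiducial set
#'
#' Skin-affixed markers used only for accuracy measurement, never for
#' registration.  Default labelling A.. follows the six-marker protocol.
#'
#' @param points n x 3 matrix of marker coordinates (mm).
#' @param labels unique labels; default \code{LETTERS[1:n]}.
#' @param frame frame label the coordinates live in.
#' @return object of class \code{fiducial_set}.
#' @export
fiducial_set <- function(points, labels = NULL, frame = "RICS") {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 3L, nrow(points) >= 1L)
  if (is.null(labels)) labels <- LETTERS[seq_len(nrow(points))]
  stopifnot(length(labels) == nrow(points), !anyDuplicated(labels))
  rownames(points) <- labels
  structure(list(points = points, labels = labels,
                 frame = frame_label(frame)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("fiducial_set: %d markers (%s) in %s\n", length(x$labels),
              paste(x$labels, collapse = ","), x$frame))
  invisible(x)
}

#' Per-point target registration error
#'
#' The Euclidean distance between each known reference point P and its
#' probed counterpart Q, with signed per-axis components for component
#' histograms.
#'
#' @param P a \code{fiducial_set} (the reference points).
#' @param Q a \code{fiducial_set} or labelled n x 3 matrix (the probed
#'   points), same labels and frame.
#' @return data.frame with columns \code{marker}, \code{dx}, \code{dy},
#'   \code{dz} (Q - P, mm) and \code{distance} (mm).
#' @export
tre <- function(P, Q) {
  stopifnot(inherits(P, "fiducial_set"))
  Qm <- if (inherits(Q, "fiducial_set")) Q$points else as.matrix(Q)
  if (is.null(rownames(Qm))) stop("probed points must carry marker labels")
  if (!setequal(rownames(Qm), P$labels))
    stop("marker label mismatch between reference and probed points")
  Qm <- Qm[P$labels, , drop = FALSE]
  D <- Qm - P$points
  data.frame(marker = P$labels, dx = D[, 1], dy = D[, 2], dz = D[, 3],
             distance = sqrt(rowSums(D^2)), row.names = NULL)
}

#' Simulate the full TRE measurement protocol
#'
#' Nested protocol: per registration an optional rigid deployment bias is
#' drawn once (translation, isotropic Gaussian), then each measurement
#' session probes every marker with independent isotropic Gaussian
#' perception noise.  The default shape (3 registrations x 3 sessions x
#' 6 markers = 54 points) matches the phantom study design.
#'
#' @param P a \code{fiducial_set} of reference points (RICS frame).
#' @param n_registrations,n_sessions protocol shape, defaults 3 and 3.
#' @param noise_sigma per-axis probe noise sd (mm).
#' @param registration_sigma per-axis sd of the once-per-registration
#'   translation bias (mm), default 0.
#' @param seed RNG seed.
#' @return object of class \code{tre_report}: data.frame with columns
#'   \code{registration}, \code{session}, \code{marker}, \code{dx},
#'   \code{dy}, \code{dz}, \code{distance}.
#' @export
run_protocol <- function(P, n_registrations = 3L, n_sessions = 3L,
                         noise_sigma = 0, registration_sigma = 0,
                         seed = 20231107) {
  stopifnot(inherits(P, "fiducial_set"), n_registrations >= 1L,
            n_sessions >= 1L, noise_sigma >= 0, registration_sigma >= 0)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(P$points)
  rows <- vector("list", n_registrations * n_sessions)
  k <- 0L
  for (r in seq_len(n_registrations)) {
    bias <- stats::rnorm(3L, 0, registration_sigma)
    for (s in seq_len(n_sessions)) {
      noise <- matrix(stats::rnorm(3L * n, 0, noise_sigma), n, 3L)
      Q <- P$points + matrix(bias, n, 3L, byrow = TRUE) + noise
      rownames(Q) <- P$labels
      d <- tre(P, Q)
      k <- k + 1L
      rows[[k]] <- cbind(registration = r, session = s, d)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tre_report", "data.frame")
  out
}

#' Summarize a TRE report
#'
#' Mean, sample (n-1) standard deviation, min and max of the per-point
#' deviations, overall and grouped by registration and by marker, plus the
#' fraction of points strictly below a clinical cutoff and per-axis RMSE.
#'
#' @param report a \code{tre_report} (or compatible data.frame).
#' @param cutoff_mm acceptance cutoff (mm), default 5.
#' @return list with \code{overall} (one-row data.frame incl.
#'   \code{fraction_below_cutoff}), \code{by_registration},
#'   \code{by_marker}, and \code{axis_rmse}.
#' @export
summarize_tre <- function(report, cutoff_mm = 5) {
  stopifnot(nrow(report) > 0L)
  smry <- function(x) data.frame(n = length(x), mean = mean(x),
                                 sd = stats::sd(x), min = min(x),
                                 max = max(x))
  overall <- smry(report$distance)
  overall$fraction_below_cutoff <- mean(report$distance < cutoff_mm)
  by_reg <- do.call(rbind, lapply(split(report$distance,
                                        report$registration), smry))
  by_reg <- cbind(registration = as.integer(rownames(by_reg)), by_reg)
  rownames(by_reg) <- NULL
  by_mark <- do.call(rbind, lapply(split(report$distance, report$marker),
                                   smry))
  by_mark <- cbind(marker = rownames(by_mark), by_mark)
  rownames(by_mark) <- NULL
  list(overall = overall, by_registration = by_reg, by_marker = by_mark,
       axis_rmse = c(x = sqrt(mean(report$dx^2)),
                     y = sqrt(mean(report$dy^2)),
                     z = sqrt(mean(report$dz^2))))
}

#' Write a TRE report to CSV
#' @param report a \code{tre_report}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
tre_report_to_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid transform between paired fiducials
#'
#' The optimal proper rigid transform minimizing the summed squared
#' distances between transformed reference points and their probed
#' counterparts (Kabsch/SVD solution, det = +1 enforced so a reflection is
#' never returned).  Used to extrapolate the full-head error distribution
#' from the six measured markers.
#'
#' @param P a \code{fiducial_set} of reference points.
#' @param Q matching probed points (\code{fiducial_set} or labelled
#'   matrix).
#' @param frame frame pair given to the result; default maps the fiducial
#'   frame onto itself.
#' @return a \code{rigid_transform} T with \code{T(P) ~ Q}, with attribute
#'   \code{"rms_mm"} carrying the root-mean-square residual.
#' @export
fit_rigid_lsq <- function(P, Q, frame = NULL) {
  stopifnot(inherits(P, "fiducial_set"))
  Qm <- if (inherits(Q, "fiducial_set")) Q$points else as.matrix(Q)
  if (is.null(rownames(Qm))) stop("probed points must carry marker labels")
  if (!setequal(rownames(Qm), P$labels)) stop("marker label mismatch")
  Qm <- Qm[P$labels, , drop = FALSE]
  Pm <- P$points
  if (nrow(Pm) < 3L) stop("need at least 3 point pairs")
  cp <- colMeans(Pm); cq <- colMeans(Qm)
  X <- sweep(Pm, 2L, cp); Y <- sweep(Qm, 2L, cq)
  sv <- svd(crossprod(X, Y))
  ## collinearity guard: rank of the centred reference configuration
  if (svd(X)$d[2] < 1e-9 * max(svd(X)$d[1], 1))
    stop("degenerate (collinear) fiducial configuration")
  S <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) S[3, 3] <- -1
  R <- sv$v %*% S %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  fr <- if (is.null(frame)) c(P$frame, P$frame) else frame
  T <- rigid_transform(fr[1], fr[2], rotation = R, translation = t)
  attr(T, "rms_mm") <- sqrt(mean(rowSums(
    (apply_transform(T, Pm) - Qm)^2)))
  T
}

#' Per-vertex model-to-model distance under a rigid transform
#'
#' Distance between each vertex of the original model and its image under
#' the fitted registration-error transform, corresponding-vertex
#' convention; the scalar field usually exported with the mesh for colour
#' mapping.
#'
#' @param mesh a \code{surface_mesh}.
#' @param T_PQ a \code{rigid_transform}.
#' @return numeric per-vertex distances (mm).
#' @export
model_to_model_distance <- function(mesh, T_PQ) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(T_PQ, "rigid_transform"))
  V2 <- apply_transform(T_PQ, mesh$vertices)
  sqrt(rowSums((V2 - mesh$vertices)^2))
}

#' One-way fixed-effects ANOVA across groups of deviations
#'
#' Classical F test with df (k-1, N-k), equal variances assumed, as used
#' to compare TREs between registrations and between markers.  When every
#' observation is identical across all groups the statistic is defined as
#' 0 with p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 samples).
#' @return list with \code{F}, \code{p}, and \code{df} (length 2).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups); N <- length(x)
  if (stats::var(x) < 1e-30)
    return(list(F = 0, p = 1, df = c(k - 1L, N - k)))
  ht <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(c(ht$parameter[1], ht$parameter[2])))
}
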