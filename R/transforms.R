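#' @keywords internal
"_PACKAGE"

## Coordinate frames of the simulator-based registration chain.
FRAME_LABELS <- c("WORLD", "SCANNER", "RICS", "SCS", "VCS", "HMD")

#' Validate a coordinate frame label
#'
#' The registration chain uses six named right-handed frames: \code{WORLD}
#' (the tracking/world frame of the head-mounted display), \code{SCANNER}
#' (the mechanical frame of the CT/MRI gantry), \code{RICS} (reference image
#' coordinate system fixed by the gantry laser lines at acquisition),
#' \code{SCS} (simulator coordinate system defined by the three orthogonal
#' laser planes), \code{VCS} (virtual frame anchored to the tracked image
#' target) and \code{HMD} (the headset frame).
#'
#' @param name character scalar, one of the six labels.
#' @return the validated label (character scalar).
#' @export
frame_label <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% FRAME_LABELS))
    stop("unknown frame label: ", paste(name, collapse = ", "),
         " (expected one of ", paste(FRAME_LABELS, collapse = ", "), ")")
  name
}

## --- construction helpers ---------------------------------------------------

#' Rotation matrix from a rotation vector (axis-angle)
#'
#' Rodrigues' formula.  The rotation vector's direction is the axis and its
#' Euclidean norm the angle in radians; the zero vector gives the identity.
#'
#' @param rv numeric length-3 rotation vector (radians).
#' @return 3x3 proper rotation matrix.
#' @export
rotvec_to_matrix <- function(rv) {
  stopifnot(is.numeric(rv), length(rv) == 3L, all(is.finite(rv)))
  theta <- sqrt(sum(rv^2))
  if (theta < 1e-12) {
    ## second-order series keeps derivatives smooth near identity
    K <- skew3(rv)
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  k <- rv / theta
  K <- skew3(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation vector from a rotation matrix
#'
#' Inverse of \code{\link{rotvec_to_matrix}}; returns the minimal rotation
#' vector (angle in [0, pi]).
#'
#' @param R 3x3 proper rotation matrix.
#' @return numeric length-3 rotation vector (radians).
#' @export
matrix_to_rotvec <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) {
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
    return(w)
  }
  if (theta > pi - 1e-6) {
    ## near pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    ## fix signs using the largest component
    i <- which.max(axis)
    if (axis[i] > 0) {
      s <- sign(A[i, ] / axis[i])
      s[i] <- 1
      axis <- abs(axis) * ifelse(s == 0, 1, s)
    }
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  w / (2 * sin(theta)) * theta
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

## Nearest rotation by polar decomposition (SVD), det forced to +1.
project_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Construct a proper rigid transform between two named frames
#'
#' A rigid transform maps points expressed in the \code{source} frame into
#' the \code{target} frame by \code{p' = R p + t} (column-vector convention,
#' millimetres).  Internally a homogeneous 4x4 matrix is stored.  Rotation
#' input may be a 3x3 matrix or a rotation vector; near-orthogonal matrices
#' (within 1e-6 of orthogonality) are re-projected by polar decomposition,
#' anything further off is rejected, as are reflections.
#'
#' @param source,target frame labels (see \code{\link{frame_label}}).
#' @param rotation 3x3 rotation matrix, or length-3 rotation vector in
#'   radians; default identity.
#' @param translation length-3 translation in mm; default zero.
#' @return object of class \code{rigid_transform}.
#' @examples
#' T1 <- rigid_transform("RICS", "WORLD", rotation = c(0, 0, pi / 2),
#'                       translation = c(1, 0, 0))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(source, target, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  source <- frame_label(source)
  target <- frame_label(target)
  if (is.numeric(rotation) && is.null(dim(rotation)) && length(rotation) == 3L)
    rotation <- rotvec_to_matrix(rotation)
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            all(is.finite(rotation)),
            is.numeric(translation), length(translation) == 3L,
            all(is.finite(translation)))
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6)
    stop("rotation is not orthonormal (max deviation ", format(err), ")")
  if (det(rotation) < 0)
    stop("rotation has det < 0: reflections are not rigid transforms")
  if (err > 1e-12) rotation <- project_rotation(rotation)
  M <- diag(4)
  M[1:3, 1:3] <- rotation
  M[1:3, 4] <- translation
  structure(list(source = source, target = target, matrix = M),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform [%s -> %s]\n", x$source, x$target))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Rotation block of a rigid transform
#' @param T a \code{rigid_transform}.
#' @return 3x3 rotation matrix.
#' @export
rotation_of <- function(T) T$matrix[1:3, 1:3]

#' Translation of a rigid transform
#' @param T a \code{rigid_transform}.
#' @return length-3 translation (mm).
#' @export
translation_of <- function(T) T$matrix[1:3, 4]

#' Identity transform on a frame
#' @param frame frame label.
#' @return \code{rigid_transform} mapping \code{frame} to itself.
#' @export
identity_transform <- function(frame) rigid_transform(frame, frame)

#' Compose two rigid transforms
#'
#' \code{compose(first, second)} returns the transform applying \code{first}
#' then \code{second}; the product convention is "left factor applied after
#' the right", i.e. the result's matrix is \code{second . first}.  The frames
#' must chain: \code{first} maps A to B, \code{second} maps B to C.
#'
#' @param first \code{rigid_transform} A -> B.
#' @param second \code{rigid_transform} B -> C.
#' @return \code{rigid_transform} A -> C.
#' @export
compose <- function(first, second) {
  stopifnot(inherits(first, "rigid_transform"),
            inherits(second, "rigid_transform"))
  if (!identical(first$target, second$source))
    stop("frame mismatch in compose(): first maps to '", first$target,
         "' but second maps from '", second$source, "'")
  M <- second$matrix %*% first$matrix
  out <- rigid_transform(first$source, second$target,
                         rotation = M[1:3, 1:3], translation = M[1:3, 4])
  out
}

#' Invert a rigid transform
#'
#' @param T a \code{rigid_transform} A -> B.
#' @return the inverse transform B -> A (rotation transposed, translation
#'   \code{-R't}).
#' @export
invert <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  R <- rotation_of(T)
  t <- translation_of(T)
  rigid_transform(T$target, T$source, rotation = t(R),
                  translation = -as.vector(crossprod(R, t)))
}

#' Apply a rigid transform to points
#'
#' @param T a \code{rigid_transform}.
#' @param points numeric length-3 vector or n x 3 matrix of points (mm) in
#'   the source frame.
#' @return points in the target frame, same shape as the input.
#' @export
apply_transform <- function(T, points) {
  stopifnot(inherits(T, "rigid_transform"))
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1L, 3L)
  stopifnot(is.numeric(points), ncol(points) == 3L)
  if (!all(is.finite(points))) stop("non-finite coordinates in points")
  out <- points %*% t(rotation_of(T))
  out <- sweep(out, 2L, translation_of(T), "+")
  if (vec) as.vector(out) else out
}

## --- frame graph ------------------------------------------------------------

#' Create a frame graph
#'
#' A container for the transforms of the registration chain, keyed by
#' ordered (source, target) pair.  Querying a reversed pair returns the
#' inverse of the stored edge.
#'
#' @param ... \code{rigid_transform} objects to add.
#' @return object of class \code{frame_graph}.
#' @export
frame_graph <- function(...) {
  g <- structure(list(edges = list()), class = "frame_graph")
  for (T in list(...)) g <- add_edge(g, T)
  g
}

edge_key <- function(source, target) paste(source, target, sep = "->")

#' Add a transform edge to a frame graph
#'
#' At most one edge may be stored per ordered frame pair (in either
#' direction); adding a duplicate replaces both directions' view of it.
#'
#' @param g a \code{frame_graph}.
#' @param T a \code{rigid_transform}.
#' @return the updated graph.
#' @export
add_edge <- function(g, T) {
  stopifnot(inherits(g, "frame_graph"), inherits(T, "rigid_transform"))
  g$edges[[edge_key(T$target, T$source)]] <- NULL
  g$edges[[edge_key(T$source, T$target)]] <- T
  g
}

#' Look up a transform between two frames
#'
#' Returns the stored edge for (source, target), or the inverse of the
#' stored (target, source) edge.
#'
#' @param g a \code{frame_graph}.
#' @param source,target frame labels.
#' @return a \code{rigid_transform}, or an error if no edge exists.
#' @export
get_edge <- function(g, source, target) {
  source <- frame_label(source); target <- frame_label(target)
  T <- g$edges[[edge_key(source, target)]]
  if (!is.null(T)) return(T)
  T <- g$edges[[edge_key(target, source)]]
  if (!is.null(T)) return(invert(T))
  stop("frame graph has no transform ", source, " -> ", target)
}

## Symbolic edges of the registration chain, in application order
## (rightmost applied first): T_WH, T_HV, T_VR, T_RS, T_SSc.
CHAIN_EDGES <- list(
  T_WH  = c("WORLD", "HMD"),
  T_HV  = c("HMD", "VCS"),
  T_VR  = c("VCS", "RICS"),
  T_RS  = c("RICS", "SCS"),
  T_SSc = c("SCS", "SCANNER"))

#' World-to-scanner transform from the full registration chain
#'
#' Resolves the five-factor product
#' \code{T_WSc = T_SSc . T_RS . T_VR . T_HV . T_WH}:
#' world to headset (SLAM), headset to virtual frame (image-target
#' tracking), virtual frame to reference image (extrinsic calibration),
#' reference image to simulator (intrinsic calibration), simulator to
#' scanner (deployment against the marked skin lines).
#'
#' @param g a \code{frame_graph} containing the five chain edges.
#' @return \code{rigid_transform} WORLD -> SCANNER.
#' @export
chain_world_to_scanner <- function(g) {
  stopifnot(inherits(g, "frame_graph"))
  acc <- NULL
  for (nm in names(CHAIN_EDGES)) {
    fr <- CHAIN_EDGES[[nm]]
    T <- tryCatch(get_edge(g, fr[1], fr[2]), error = function(e)
      stop("chain is missing transform ", nm, " (", fr[1], " -> ", fr[2], ")",
           call. = FALSE))
    acc <- if (is.null(acc)) T else compose(acc, T)
  }
  acc
}

## --- serialization ----------------------------------------------------------

#' Serialize a rigid transform to a JSON string
#'
#' Format: \code{{"source", "target", "matrix"}} with the homogeneous 4x4
#' matrix flattened row-major to 16 numbers.
#'
#' @param T a \code{rigid_transform}.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to file.
#' @export
transform_to_json <- function(T, path = NULL) {
  stopifnot(inherits(T, "rigid_transform"))
  obj <- list(source = T$source, target = T$target,
              matrix = as.vector(t(T$matrix)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a rigid transform from JSON
#'
#' @param x JSON string, or path to a JSON file.
#' @return a \code{rigid_transform}.
#' @export
transform_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  M <- matrix(obj$matrix, 4, 4, byrow = TRUE)
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("homogeneous matrix last row must be (0,0,0,1)")
  rigid_transform(obj$source, obj$target,
                  rotation = M[1:3, 1:3], translation = M[1:3, 4])
}

## Angle (rad) between two rotations; used throughout for error reporting.
rotation_angle_between <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, ct)))
}

#' Pose difference between two rigid transforms
#'
#' @param A,B \code{rigid_transform}s over the same frame pair.
#' @return list with \code{translation_mm} (Euclidean distance between the
#'   translations) and \code{rotation_deg} (relative rotation angle).
#' @export
pose_difference <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  list(translation_mm = sqrt(sum((translation_of(A) - translation_of(B))^2)),
       rotation_deg = rotation_angle_between(rotation_of(A), rotation_of(B)) *
         180 / pi)
}

## Random rigid transform, used by tests and simulations. Rotation drawn
## uniformly (axis uniform on sphere, angle uniform), translation uniform
## in [-range, range]^3.
#' Draw a random rigid transform
#' @param source,target frame labels.
#' @param max_angle maximal rotation angle (radians).
#' @param max_translation maximal per-axis translation (mm).
#' @return a \code{rigid_transform}.  Uses the current RNG stream.
#' @export
random_rigid_transform <- function(source, target, max_angle = pi,
                                   max_translation = 100) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_angle)
  tr <- stats::runif(3, -max_translation, max_translation)
  rigid_transform(source, target, rotation = ax * ang, translation = tr)
}
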