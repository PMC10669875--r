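## Scan geometry of the reference image and scanner-marked laser lines.
## Patient axes follow the LPS convention (x left, y posterior, z superior).

#' Scan geometry of the reference image
#'
#' @param fov_mm length-2 in-plane field of view (mm).
#' @param matrix_size length-2 in-plane acquisition matrix (counts).
#' @param slice_thickness_mm slice thickness (mm).
#' @param n_slices number of slices.
#' @return object of class \code{scan_geometry}.
#' @examples
#' g <- scan_geometry(c(251, 251), c(128, 128), 0.625, 256)
#' voxel_spacing(g)   # 1.96 1.96 0.625 (in-plane rounded to 2 decimals)
#' @export
scan_geometry <- function(fov_mm, matrix_size, slice_thickness_mm, n_slices) {
  stopifnot(is.numeric(fov_mm), length(fov_mm) == 2L, all(fov_mm > 0),
            is.numeric(matrix_size), length(matrix_size) == 2L,
            all(matrix_size > 0), all(matrix_size == round(matrix_size)),
            is.numeric(slice_thickness_mm), slice_thickness_mm > 0,
            n_slices > 0, n_slices == round(n_slices))
  structure(list(fov_mm = as.numeric(fov_mm),
                 matrix_size = as.integer(matrix_size),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 n_slices = as.integer(n_slices)),
            class = "scan_geometry")
}

#' Voxel spacing of a scan geometry
#'
#' In-plane spacing is FOV divided by matrix size, reported rounded to two
#' decimals as scanner consoles print it; through-plane spacing is the
#' slice thickness.
#'
#' @param g a \code{scan_geometry}.
#' @param digits decimals for the in-plane spacing; \code{NULL} disables
#'   rounding.
#' @return length-3 numeric (x, y, z spacing in mm).
#' @export
voxel_spacing <- function(g, digits = 2) {
  stopifnot(inherits(g, "scan_geometry"))
  if (any(g$matrix_size == 0L)) stop("zero acquisition matrix entry")
  inplane <- g$fov_mm / g$matrix_size
  if (!is.null(digits)) inplane <- round(inplane, digits)
  c(inplane, g$slice_thickness_mm)
}

#' Read a scan geometry from a JSON config
#' @param x JSON string or path with fields \code{fov_mm},
#'   \code{matrix_size}, \code{slice_thickness_mm}, \code{n_slices}.
#' @return a \code{scan_geometry}.
#' @export
scan_geometry_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  scan_geometry(obj$fov_mm, obj$matrix_size, obj$slice_thickness_mm,
                obj$n_slices)
}

#' A plane in Hesse normal form
#' @param normal length-3 normal vector (normalized internally).
#' @param offset signed distance of the plane from the origin (mm).
#' @return object of class \code{plane}.
#' @export
plane <- function(normal, offset = 0) {
  stopifnot(is.numeric(normal), length(normal) == 3L, all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("plane normal must be non-zero")
  structure(list(normal = normal / nn, offset = as.numeric(offset)),
            class = "plane")
}

#' Signed distance from points to a plane
#' @param pl a \code{plane}.
#' @param points length-3 vector or n x 3 matrix.
#' @return signed distances (mm), positive on the normal side.
#' @export
plane_distance <- function(pl, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L, 3L)
  as.vector(points %*% pl$normal) - pl$offset
}

#' The three orthogonal reference planes of the reference image frame
#'
#' The reference image coordinate system is fixed where the gantry laser
#' positioning lines are projected at acquisition; its reference planes
#' are the three coordinate planes through its origin, normals along the
#' frame axes (sagittal x, coronal y, axial z).
#'
#' @param origin_frame frame label; must be \code{"RICS"}.
#' @return named list of three \code{plane}s (sagittal, coronal, axial).
#' @export
reference_planes <- function(origin_frame = "RICS") {
  if (!identical(frame_label(origin_frame), "RICS"))
    stop("reference planes are defined in the RICS frame")
  list(sagittal = plane(c(1, 0, 0), 0),
       coronal = plane(c(0, 1, 0), 0),
       axial = plane(c(0, 0, 1), 0))
}

#' Mark the scanner's laser positioning lines on a surface
#'
#' Intersects the three reference planes of the posed reference-image frame
#' with a head surface, keeps the laser-visible side (sagittal and coronal
#' lines lit from above, axial and coronal lines from the side), and
#' resamples the polylines at a fixed step.  These are the skin lines drawn
#' at acquisition that later guide simulator deployment.
#'
#' @param surface a \code{surface_mesh} in world coordinates.
#' @param scanner_pose \code{rigid_transform} RICS -> WORLD.
#' @param step_mm resampling step along the curves (mm), default 0.5.
#' @return a \code{crosshair_curves} ("marked lines"); labels with no
#'   intersection are flagged empty (see field \code{empty}).
#' @export
mark_reference_lines <- function(surface, scanner_pose, step_mm = 0.5) {
  stopifnot(inherits(surface, "surface_mesh"),
            inherits(scanner_pose, "rigid_transform"), step_mm > 0)
  if (!identical(scanner_pose$target, "WORLD"))
    stop("scanner_pose must map into the WORLD frame")
  out <- project_planes_on_mesh(surface, scanner_pose, step_mm)
  if (any(out$empty))
    warning("reference plane(s) ", paste(names(which(out$empty)),
            collapse = ", "), " do not intersect the surface")
  out
}
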