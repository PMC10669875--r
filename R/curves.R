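## Labelled polyline sets on a surface: scanner-marked reference lines and
## simulator crosshair projections share this representation.

## roles of the three orthogonal planes, by frame axis carrying the normal
PLANE_ROLES <- c(sagittal = 1L, coronal = 2L, axial = 3L)

new_crosshair_curves <- function(curves, frame, step) {
  empty <- vapply(curves, function(comps)
    length(comps) == 0L || all(vapply(comps, function(cp)
      nrow(cp$points) < 2L, TRUE)), TRUE)
  structure(list(curves = curves, frame = frame, step = step, empty = empty),
            class = "crosshair_curves")
}

#' @export
print.crosshair_curves <- function(x, ...) {
  cat(sprintf("crosshair_curves in frame %s (step %.3g mm)\n", x$frame, x$step))
  for (lb in names(x$curves)) {
    comps <- x$curves[[lb]]
    L <- sum(vapply(comps, function(cp)
      polyline_length(cp$points, isTRUE(cp$closed)), 0))
    cat(sprintf("  %-10s %d component(s), total length %.2f mm%s\n", lb,
                length(comps), L, if (x$empty[[lb]]) "  [empty]" else ""))
  }
  invisible(x)
}

#' Total polyline length per curve label
#' @param curves a \code{crosshair_curves} object.
#' @return named numeric vector of lengths (mm).
#' @export
curve_lengths <- function(curves) {
  vapply(curves$curves, function(comps)
    sum(vapply(comps, function(cp)
      polyline_length(cp$points, isTRUE(cp$closed)), 0)), 0)
}

## Project the three coordinate planes of a posed frame onto a mesh,
## clip to the laser-visible side, resample. The shared engine behind
## mark_reference_lines() and project_crosshair().
##
## pose: rigid_transform frame -> WORLD; mesh in world coordinates.
## emitters: list(top = position, side = position) in the posed frame.
## Visibility: sagittal lines from the top emitter, axial lines from the
## side emitter, coronal lines from either (the shared plane is lit by
## both crosshairs).
project_planes_on_mesh <- function(mesh, pose, step,
                                   emitters = default_emitters(),
                                   plane_normals = diag(3),
                                   resample = TRUE) {
  R <- rotation_of(pose)
  origin <- translation_of(pose)
  em_world <- lapply(emitters, function(p) as.vector(apply_transform(pose, p)))
  vis_map <- list(sagittal = "top", coronal = c("top", "side"),
                  axial = "side")
  curves <- list()
  for (lb in names(PLANE_ROLES)) {
    n_local <- plane_normals[PLANE_ROLES[[lb]], ]
    n_w <- as.vector(R %*% n_local)
    off <- sum(n_w * origin)
    comps <- plane_mesh_intersection(mesh, n_w, off)
    if (length(comps) > 0L) {
      keep <- list()
      for (cp in comps) {
        best <- NULL
        for (which_em in vis_map[[lb]]) {
          cl <- clip_components_visible(list(cp), em_world[[which_em]])
          if (length(cl) > 0L) best <- c(best, cl)
        }
        ## merge visibility from multiple emitters: union of visible runs;
        ## overlapping runs are acceptable for distance-based misfit
        keep <- c(keep, best)
      }
      comps <- keep
    }
    if (resample && length(comps) > 0L) {
      comps <- lapply(comps, function(cp) {
        P <- resample_polyline(cp$points, step, isTRUE(cp$closed))
        list(points = P, closed = FALSE)
      })
      lens <- vapply(comps, function(cp) polyline_length(cp$points), 0)
      comps <- comps[lens >= 2 * step]
    }
    curves[[lb]] <- comps
  }
  new_crosshair_curves(curves, "WORLD", step)
}

default_emitters <- function(top_distance = 400, side_distance = 400) {
  list(top = c(0, 0, top_distance), side = c(side_distance, 0, 0))
}

## Pool vertices of all components for a set of labels.
curve_points <- function(curves, labels = names(curves$curves)) {
  do.call(rbind, unlist(lapply(labels, function(lb)
    lapply(curves$curves[[lb]], `[[`, "points")), recursive = FALSE))
}

#' Symmetric mean closest-point distance between labelled curve sets
#'
#' For each shared label, the mean distance from each vertex of one side to
#' the polyline segments of the other, symmetrized by averaging the two
#' directed means.  Zero iff the curves coincide within sampling tolerance.
#'
#' @param a,b \code{crosshair_curves} objects (same frame).
#' @param labels labels to compare; defaults to all labels present on both
#'   sides.  An error is raised if a requested label is missing or empty on
#'   either side.
#' @return misfit in mm.
#' @export
curve_misfit <- function(a, b, labels = NULL) {
  stopifnot(inherits(a, "crosshair_curves"), inherits(b, "crosshair_curves"))
  if (is.null(labels)) labels <- intersect(names(a$curves), names(b$curves))
  if (length(labels) == 0L)
    stop("no shared curve labels between the two sides")
  for (lb in labels) {
    if (is.null(a$curves[[lb]]) || is.null(b$curves[[lb]]))
      stop("curve label '", lb, "' missing on one side")
    if (isTRUE(a$empty[[lb]]) || isTRUE(b$empty[[lb]]))
      stop("curve label '", lb, "' is empty; cannot compute misfit")
  }
  d_ab <- directed_curve_distances(a, b, labels)
  d_ba <- directed_curve_distances(b, a, labels)
  (mean(d_ab) + mean(d_ba)) / 2
}

## distances from every vertex of `from` to the segments of `to`, per label
directed_curve_distances <- function(from, to, labels) {
  unlist(lapply(labels, function(lb) {
    P <- curve_points(from, lb)
    segs <- components_segments(to$curves[[lb]])
    if (is.null(segs)) stop("no segments for label '", lb, "'")
    points_to_segments_distance(P, segs)
  }))
}

#' Hausdorff distance between labelled curve sets
#'
#' Symmetric Hausdorff (max-min) distance pooled over labels; a stricter
#' diagnostic companion to the mean-based \code{\link{curve_misfit}}.
#' @inheritParams curve_misfit
#' @return distance in mm.
#' @export
curve_hausdorff <- function(a, b, labels = NULL) {
  if (is.null(labels)) labels <- intersect(names(a$curves), names(b$curves))
  max(max(directed_curve_distances(a, b, labels)),
      max(directed_curve_distances(b, a, labels)))
}

## --- CSV / JSON serialization ----------------------------------------------

#' Write labelled curves to CSV
#'
#' Columns: curve_id (label#component), point_index, x, y, z.
#' @param curves a \code{crosshair_curves}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
curves_to_csv <- function(curves, path) {
  rows <- list()
  for (lb in names(curves$curves)) {
    comps <- curves$curves[[lb]]
    for (k in seq_along(comps)) {
      P <- comps[[k]]$points
      if (nrow(P) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        curve_id = paste0(lb, "#", k), point_index = seq_len(nrow(P)),
        x = P[, 1], y = P[, 2], z = P[, 3])
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read labelled curves from CSV
#' @param path CSV written by \code{\link{curves_to_csv}}.
#' @param frame frame label of the coordinates.
#' @param step sampling step recorded on the object (mm).
#' @return a \code{crosshair_curves}.
#' @export
curves_from_csv <- function(path, frame = "WORLD", step = 0.5) {
  df <- utils::read.csv(path)
  labels <- sub("#.*$", "", df$curve_id)
  curves <- list()
  for (lb in unique(labels)) {
    sub <- df[labels == lb, , drop = FALSE]
    comps <- lapply(split(sub, sub$curve_id), function(g) {
      g <- g[order(g$point_index), , drop = FALSE]
      list(points = as.matrix(g[, c("x", "y", "z")]), closed = FALSE)
    })
    names(comps) <- NULL
    curves[[lb]] <- comps
  }
  new_crosshair_curves(curves, frame, step)
}
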