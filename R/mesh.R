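## Triangulated surface meshes and plane-mesh intersection geometry.
## Plane-mesh contouring is the geometric primitive behind both the
## scanner's skin-line marking and the simulator's crosshair projection.

#' Construct a triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, oriented
#'   counter-clockwise when seen from outside.
#' @return object of class \code{surface_mesh} with per-vertex unit normals
#'   (area-weighted average of incident face normals).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(is.numeric(vertices), ncol(vertices) == 3L,
            all(is.finite(vertices)),
            ncol(faces) == 3L, all(faces == round(faces)),
            min(faces) >= 1L, max(faces) <= nrow(vertices))
  storage.mode(faces) <- "integer"
  fn <- face_normals_raw(vertices, faces)
  areas <- sqrt(rowSums(fn^2)) / 2
  if (any(areas <= 1e-9))
    stop("mesh contains degenerate faces (area <= 1e-9 mm^2)")
  vn <- matrix(0, nrow(vertices), 3L)
  for (k in 1:3) {
    idx <- faces[, k]
    vn[, 1] <- vn[, 1] + tabulate2(idx, fn[, 1], nrow(vertices))
    vn[, 2] <- vn[, 2] + tabulate2(idx, fn[, 2], nrow(vertices))
    vn[, 3] <- vn[, 3] + tabulate2(idx, fn[, 3], nrow(vertices))
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm < 1e-30] <- 1
  vn <- vn / nrm
  structure(list(vertices = vertices, faces = faces, normals = vn),
            class = "surface_mesh")
}

## un-normalized face normals (cross products; norm = 2*area)
face_normals_raw <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cross3(b - a, c - a)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

## sum weights w by integer index into a length-n vector
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  tmp <- rowsum(w, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Transform a surface mesh by a rigid transform
#' @param mesh a \code{surface_mesh}.
#' @param T a \code{rigid_transform}; vertices are mapped by it and normals
#'   rotated.
#' @return the transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, T) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- apply_transform(T, mesh$vertices)
  out <- mesh
  out$vertices <- V
  out$normals <- mesh$normals %*% t(rotation_of(T))
  out
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed genus-0 surface.
#' @param mesh a \code{surface_mesh}.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  nE <- nrow(unique(e))
  nrow(mesh$vertices) - nE + nrow(F)
}

#' Estimate per-vertex curvature radius
#'
#' A discrete estimate from normal variation: for each mesh edge (i, j) the
#' local radius is |p_i - p_j| / angle(n_i, n_j); each vertex gets the
#' median over its incident edges.  Crude, but monotone in true curvature
#' on smooth synthetic surfaces, which is all it is used for.
#'
#' @param mesh a \code{surface_mesh}.
#' @return numeric vector of per-vertex radius estimates (mm); \code{Inf}
#'   where the surface is locally flat.
#' @export
vertex_curvature_radius <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  p <- mesh$vertices; n <- mesh$normals
  d <- sqrt(rowSums((p[e[, 1], ] - p[e[, 2], ])^2))
  ct <- rowSums(n[e[, 1], ] * n[e[, 2], ])
  ang <- acos(pmin(1, pmax(-1, ct)))
  r <- ifelse(ang < 1e-9, Inf, d / ang)
  out <- rep(Inf, nrow(p))
  for (col in 1:2) {
    sp <- split(r, e[, col])
    ids <- as.integer(names(sp))
    med <- vapply(sp, stats::median, 0)
    out[ids] <- pmin(out[ids], med, na.rm = TRUE)
  }
  out
}

## --- STL / OBJ ASCII I/O ----------------------------------------------------

#' Write a mesh as ASCII STL
#' @param mesh a \code{surface_mesh}.
#' @param path output file path.
#' @param name solid name written in the header.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, name = "crosshairsim") {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  fn <- face_normals_raw(V, F)
  fn <- fn / sqrt(rowSums(fn^2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  fmt <- function(p) sprintf("      vertex %.9g %.9g %.9g",
                             p[, 1], p[, 2], p[, 3])
  block <- paste(sprintf("  facet normal %.9g %.9g %.9g",
                         fn[, 1], fn[, 2], fn[, 3]),
                 "    outer loop", fmt(a), fmt(b), fmt(c),
                 "    endloop", "  endfacet", sep = "\n")
  writeLines(block, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices are merged by exact coordinate match of their printed
#' representation, so a write/read round trip reproduces the topology.
#'
#' @param path STL file path.
#' @return a \code{surface_mesh}.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(coords) %% 3L != 0L) stop("malformed STL: vertex count not 3*faces")
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  V <- coords[uk, , drop = FALSE]
  F <- matrix(ids, ncol = 3L, byrow = TRUE)
  surface_mesh(V, F)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output file path.
#' @param vertex_scalar optional per-vertex scalar (e.g. a distance field);
#'   written as an extra column on the \code{v} lines, the common extension
#'   viewers use for per-vertex attributes.
#' @return the path, invisibly.
#' @export
write_obj <- function(mesh, path, vertex_scalar = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices
  vlines <- if (is.null(vertex_scalar)) {
    sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
  } else {
    stopifnot(length(vertex_scalar) == nrow(V))
    sprintf("v %.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], vertex_scalar)
  }
  flines <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                    mesh$faces[, 3])
  writeLines(c("# crosshairsim mesh", vlines, flines), path)
  invisible(path)
}

#' Read a Wavefront OBJ file (triangles only)
#' @param path OBJ file path.
#' @return a \code{surface_mesh}; a fourth number on \code{v} lines, if
#'   present, is returned in attribute \code{"vertex_scalar"}.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vt <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  V <- do.call(rbind, lapply(vt, function(p) as.numeric(p[2:4])))
  sc <- vapply(vt, function(p) if (length(p) >= 5) as.numeric(p[5]) else NA_real_, 0)
  ft <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  F <- do.call(rbind, lapply(ft, function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  m <- surface_mesh(V, F)
  if (!all(is.na(sc))) attr(m, "vertex_scalar") <- sc
  m
}

## --- plane-mesh intersection ------------------------------------------------

## Intersect the plane {p : n.p = offset} with a mesh. Returns a list of
## polyline components, each list(points, normals, closed). Intersection
## points are keyed by the mesh edge they lie on, so chaining across
## adjacent triangles is exact. Vertices lying on the plane are nudged by
## eps toward the positive side to break ties.
plane_mesh_intersection <- function(mesh, normal, offset, eps = 1e-9) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.vector(V %*% normal) - offset
  d[abs(d) < eps] <- eps
  s <- d > 0
  cross_mask <- (s[F[, 1]] + s[F[, 2]] + s[F[, 3]])
  keep <- cross_mask == 1L | cross_mask == 2L
  if (!any(keep)) return(list())
  Fk <- F[keep, , drop = FALSE]
  ## per kept triangle, the two crossing edges
  segs_a <- matrix(0L, nrow(Fk), 2L)  # edge 1 (i,j) vertex ids
  segs_b <- matrix(0L, nrow(Fk), 2L)
  el <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  cnt <- integer(nrow(Fk))
  for (e in el) {
    i <- Fk[, e[1]]; j <- Fk[, e[2]]
    cr <- s[i] != s[j]
    first <- cr & cnt == 0L
    second <- cr & cnt == 1L
    segs_a[first, ] <- cbind(i, j)[first, , drop = FALSE]
    segs_b[second, ] <- cbind(i, j)[second, , drop = FALSE]
    cnt <- cnt + as.integer(cr)
  }
  ok <- cnt == 2L
  segs_a <- segs_a[ok, , drop = FALSE]
  segs_b <- segs_b[ok, , drop = FALSE]
  if (nrow(segs_a) == 0L) return(list())
  ## undirected edge key
  ek <- function(m) {
    lo <- pmin(m[, 1], m[, 2]); hi <- pmax(m[, 1], m[, 2])
    paste(lo, hi)
  }
  ka <- ek(segs_a); kb <- ek(segs_b)
  keys <- unique(c(ka, kb))
  ia <- match(ka, keys); ib <- match(kb, keys)
  ## intersection point + interpolated normal per unique edge
  em <- do.call(rbind, strsplit(keys, " "))
  i <- as.integer(em[, 1]); j <- as.integer(em[, 2])
  t <- d[i] / (d[i] - d[j])
  P <- V[i, , drop = FALSE] * (1 - t) + V[j, , drop = FALSE] * t
  N <- mesh$normals[i, , drop = FALSE] * (1 - t) +
    mesh$normals[j, , drop = FALSE] * t
  nn <- sqrt(rowSums(N^2)); nn[nn < 1e-30] <- 1
  N <- N / nn
  chain_segments(ia, ib, P, N)
}

## Chain segments (node index pairs) into polyline components.
chain_segments <- function(ia, ib, P, N) {
  nnode <- nrow(P)
  ## adjacency: each node appears in at most 2 segments on a manifold mesh
  adj <- vector("list", nnode)
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  deg <- lengths(adj)
  visited <- logical(nnode)
  comps <- list()
  walk <- function(start) {
    path <- start
    visited[start] <<- TRUE
    cur <- start
    prev <- 0L
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      path <- c(path, nxt)
      visited[nxt] <<- TRUE
      prev <- cur
      cur <- nxt
    }
    path
  }
  ## open chains first (endpoints have degree 1)
  for (v in which(deg == 1L)) {
    if (visited[v]) next
    path <- walk(v)
    comps[[length(comps) + 1L]] <-
      list(points = P[path, , drop = FALSE],
           normals = N[path, , drop = FALSE], closed = FALSE)
  }
  ## remaining are closed loops
  for (v in which(!visited & deg > 0L)) {
    if (visited[v]) next
    path <- walk(v)
    comps[[length(comps) + 1L]] <-
      list(points = P[path, , drop = FALSE],
           normals = N[path, , drop = FALSE], closed = TRUE)
  }
  comps
}

## Split components into visible runs: keep vertices whose outward surface
## normal points toward the emitter.
clip_components_visible <- function(comps, emitter_pos) {
  out <- list()
  for (cp in comps) {
    dirs <- sweep(-cp$points, 2L, emitter_pos, "+")
    vis <- rowSums(cp$normals * dirs) > 0
    pts <- cp$points
    if (cp$closed && all(vis)) {
      out[[length(out) + 1L]] <- list(points = pts, closed = TRUE)
      next
    }
    if (cp$closed && any(vis)) {
      ## rotate so a non-visible vertex comes first, then treat as open
      first_bad <- which(!vis)[1L]
      ord <- c(first_bad:nrow(pts), seq_len(first_bad - 1L))
      pts <- pts[ord, , drop = FALSE]
      vis <- vis[ord]
    }
    if (!any(vis)) next
    r <- rle(vis)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (r$lengths[k] < 2L) next
      out[[length(out) + 1L]] <-
        list(points = pts[starts[k]:ends[k], , drop = FALSE], closed = FALSE)
    }
  }
  out
}

## --- polyline utilities -----------------------------------------------------

polyline_length <- function(P, closed = FALSE) {
  if (nrow(P) < 2L) return(0)
  d <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  L <- sum(d)
  if (closed) L <- L + sqrt(sum((P[1L, ] - P[nrow(P), ])^2))
  L
}

## Arc-length resampling at a fixed step.
resample_polyline <- function(P, step, closed = FALSE) {
  if (closed) P <- rbind(P, P[1L, , drop = FALSE])
  if (nrow(P) < 2L) return(P)
  seg <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < step) return(P[c(1L, nrow(P)), , drop = FALSE])
  n <- max(2L, ceiling(L / step) + 1L)
  ti <- seq(0, L, length.out = n)
  cbind(stats::approx(s, P[, 1], xout = ti)$y,
        stats::approx(s, P[, 2], xout = ti)$y,
        stats::approx(s, P[, 3], xout = ti)$y)
}

## Segment matrices (A = starts, B = ends) from a component list.
components_segments <- function(comps) {
  A <- list(); B <- list()
  for (cp in comps) {
    P <- cp$points
    if (nrow(P) < 2L) next
    a <- P[-nrow(P), , drop = FALSE]
    b <- P[-1L, , drop = FALSE]
    if (isTRUE(cp$closed)) {
      a <- rbind(a, P[nrow(P), , drop = FALSE])
      b <- rbind(b, P[1L, , drop = FALSE])
    }
    A[[length(A) + 1L]] <- a
    B[[length(B) + 1L]] <- b
  }
  if (length(A) == 0L) return(NULL)
  list(A = do.call(rbind, A), B = do.call(rbind, B))
}

## Min distance from each point (m x 3) to a set of segments.
points_to_segments_distance <- function(P, segs) {
  A <- segs$A; B <- segs$B
  D <- B - A
  len2 <- rowSums(D^2)
  len2[len2 < 1e-30] <- 1e-30
  m <- nrow(P); n <- nrow(A)
  best <- rep(Inf, m)
  ## chunk over segments to bound memory
  chunk <- max(1L, floor(4e6 / m))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    idx <- lo:hi
    ## t = clamp(((P - A).D) / |D|^2)
    PA1 <- outer(P[, 1], rep(1, length(idx))) -
      outer(rep(1, m), A[idx, 1])
    PA2 <- outer(P[, 2], rep(1, length(idx))) -
      outer(rep(1, m), A[idx, 2])
    PA3 <- outer(P[, 3], rep(1, length(idx))) -
      outer(rep(1, m), A[idx, 3])
    tt <- (PA1 * rep(D[idx, 1], each = m) + PA2 * rep(D[idx, 2], each = m) +
             PA3 * rep(D[idx, 3], each = m)) / rep(len2[idx], each = m)
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    E1 <- PA1 - tt * rep(D[idx, 1], each = m)
    E2 <- PA2 - tt * rep(D[idx, 2], each = m)
    E3 <- PA3 - tt * rep(D[idx, 3], each = m)
    dd <- sqrt(E1^2 + E2^2 + E3^2)
    best <- pmin(best, apply(dd, 1L, min))
  }
  best
}
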