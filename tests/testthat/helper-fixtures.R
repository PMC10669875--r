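## Shared geometric fixtures, built in code at test time.

## sphere mesh of radius R: reuse the head generator's closed topology and
## push every vertex onto the sphere
sphere_mesh <- function(radius = 60, n_theta = 96L, n_phi = 72L) {
  h <- make_head_mesh(asymmetry = 0, nose_prominence = 0, exponent = 2,
                      n_theta = n_theta, n_phi = n_phi, seed = 1L)
  V <- h$vertices / sqrt(rowSums(h$vertices^2)) * radius
  surface_mesh(V, h$faces)
}

## flat square plate z = 0, normals up
plate_mesh <- function(half = 60, step = 5) {
  xs <- seq(-half, half, by = step)
  n <- length(xs)
  g <- expand.grid(x = xs, y = xs)
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (i - 1L) * n + j
  F <- vector("list", 2L * (n - 1L)^2)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq_len(n - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    k <- k + 1L; F[[k]] <- c(a, b, d)
    k <- k + 1L; F[[k]] <- c(a, d, c)
  }
  m <- surface_mesh(V, do.call(rbind, F))
  if (mean(m$normals[, 3]) < 0)
    m <- surface_mesh(V, m$faces[, c(1L, 3L, 2L)])
  m
}

## world pose with SCS labels from an RICS->WORLD scanner pose
scs_pose_from_scanner <- function(scanner_pose) {
  rigid_transform("SCS", "WORLD", rotation = rotation_of(scanner_pose),
                  translation = translation_of(scanner_pose))
}

## perturb a pose by (mm, deg) along seeded random directions
perturb_pose <- function(pose, mm, deg, seed = 7) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  du <- rnorm(3); du <- du / sqrt(sum(du^2))
  M <- rigid_transform(pose$target, pose$target,
                       rotation = ax * deg * pi / 180,
                       translation = du * mm)
  out <- compose(pose, M)
  rigid_transform(pose$source, pose$target, rotation = rotation_of(out),
                  translation = translation_of(out))
}
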