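test_that("per-point TRE is the Euclidean distance with signed components", {
  P <- fiducial_set(rbind(c(1, 1, 1), c(0, 0, 0)), c("A", "B"))
  Q <- rbind(A = c(2, 3, 3), B = c(0, 0, 0))
  d <- tre(P, Q)
  expect_equal(d$distance, c(3, 0))
  expect_equal(unlist(d[1, c("dx", "dy", "dz")], use.names = FALSE),
               c(1, 2, 2))
  ## label-keyed: permuting probe rows changes nothing
  d2 <- tre(P, Q[c("B", "A"), ])
  expect_equal(sort(d2$distance), sort(d$distance))
  expect_error(tre(P, rbind(A = c(0, 0, 0), C = c(1, 1, 1))), "mismatch")
  ## invariant under a common rigid transform of both point sets
  Tr <- rigid_transform("RICS", "RICS", rotation = c(0.2, -0.1, 0.3),
                        translation = c(5, 5, 5))
  P2 <- fiducial_set(apply_transform(Tr, P$points), P$labels)
  Q2 <- apply_transform(Tr, Q[P$labels, ])
  expect_equal(tre(P2, Q2)$distance, d$distance, tolerance = 1e-9)
})

test_that("the measurement protocol has the nested 6 x 3 x 3 = 54 shape", {
  set.seed(1)
  P <- fiducial_set(matrix(rnorm(18, sd = 50), 6, 3))
  rep0 <- run_protocol(P, 3L, 3L, noise_sigma = 0)
  expect_equal(nrow(rep0), 54L)
  expect_lt(max(rep0$distance), 1e-6)
  rep1 <- run_protocol(P, 3L, 3L, noise_sigma = 1, seed = 9)
  expect_equal(nrow(rep1), 54L)
  expect_true(all(rep1$distance >= 0))
  ## determinism per seed
  rep2 <- run_protocol(P, 3L, 3L, noise_sigma = 1, seed = 9)
  expect_identical(rep1$distance, rep2$distance)
})

test_that("isotropic probe noise gives the chi-3 mean deviation", {
  set.seed(2)
  P <- fiducial_set(matrix(rnorm(18, sd = 50), 6, 3))
  sigma <- 2.32
  rp <- run_protocol(P, 1L, 1700L, noise_sigma = sigma, seed = 13)
  expect_equal(mean(rp$distance), sigma * 2 * sqrt(2 / pi), tolerance = 0.02)
  ## per-axis components are zero-mean with sd near sigma
  expect_equal(sd(rp$dx), sigma, tolerance = 0.05)
  expect_lt(abs(mean(rp$dy)), 0.1)
})

test_that("summaries report mean/sd/min/max and the cutoff fraction", {
  rep0 <- data.frame(registration = 1L, session = 1L,
                     marker = c("A", "B", "C"), dx = 0, dy = 0, dz = 0,
                     distance = c(3, 4, 5))
  s <- summarize_tre(rep0, cutoff_mm = 5)
  expect_equal(s$overall$mean, 4)
  expect_equal(s$overall$min, 3)
  expect_equal(s$overall$max, 5)
  expect_equal(s$overall$sd, sd(c(3, 4, 5)))
  ## cutoff is strict
  expect_equal(s$overall$fraction_below_cutoff, 2 / 3)
  expect_equal(summarize_tre(rep0, cutoff_mm = 2)$overall$
                 fraction_below_cutoff, 0)
  expect_equal(summarize_tre(rep0, cutoff_mm = 10)$overall$
                 fraction_below_cutoff, 1)
  ## grand mean equals mean of equal-size group means
  set.seed(4)
  P <- fiducial_set(matrix(rnorm(18, sd = 50), 6, 3))
  rp <- run_protocol(P, 3L, 3L, noise_sigma = 2, seed = 5)
  s2 <- summarize_tre(rp)
  expect_equal(mean(s2$by_registration$mean), s2$overall$mean,
               tolerance = 1e-12)
})

test_that("least-squares rigid fit recovers known transforms, never a reflection", {
  set.seed(6)
  P <- fiducial_set(matrix(runif(18, -50, 50), 6, 3))
  expect_equal(fit_rigid_lsq(P, P$points)$matrix, diag(4), tolerance = 1e-9)
  Tt <- rigid_transform("RICS", "RICS", rotation = c(0.1, 0.2, -0.05),
                        translation = c(3, -2, 5))
  Q <- apply_transform(Tt, P$points)
  rownames(Q) <- P$labels
  Tf <- fit_rigid_lsq(P, Q)
  expect_lt(max(abs(Tf$matrix - Tt$matrix)), 1e-9)
  expect_lt(attr(Tf, "rms_mm"), 1e-9)
  ## reflected targets still yield a proper rotation
  Qr <- P$points %*% diag(c(-1, 1, 1))
  rownames(Qr) <- P$labels
  Tr <- fit_rigid_lsq(P, Qr)
  expect_equal(det(rotation_of(Tr)), 1, tolerance = 1e-9)
  ## collinear configurations are rejected
  Pc <- fiducial_set(cbind(1:4, 2 * (1:4), 3 * (1:4)))
  expect_error(fit_rigid_lsq(Pc, Pc$points), "collinear")
})

test_that("rigid fit matches an independent optimizer-based oracle on noisy pairs", {
  set.seed(8)
  P <- fiducial_set(matrix(runif(18, -60, 60), 6, 3))
  Tt <- rigid_transform("RICS", "RICS", rotation = c(-0.2, 0.15, 0.1),
                        translation = c(4, 1, -6))
  Q <- apply_transform(Tt, P$points) + matrix(rnorm(18, 0, 0.5), 6, 3)
  rownames(Q) <- P$labels
  Tf <- fit_rigid_lsq(P, Q)
  sse <- function(par) {
    Tp <- rigid_transform("RICS", "RICS", rotation = par[1:3],
                          translation = par[4:6])
    sum((apply_transform(Tp, P$points) - Q)^2)
  }
  oracle <- optim(c(matrix_to_rotvec(rotation_of(Tt)), translation_of(Tt)),
                  sse, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(sse(c(matrix_to_rotvec(rotation_of(Tf)),
                     translation_of(Tf))), oracle$value, tolerance = 1e-6)
  ## closed form is never worse than the identity candidate
  expect_lte(6 * attr(Tf, "rms_mm")^2, sse(rep(0, 6)) + 1e-9)
})

test_that("model-to-model distance matches closed-form displacements", {
  m <- make_parabolic_surface(60, 60, n_r = 8L, n_theta = 16L)
  expect_equal(model_to_model_distance(m, identity_transform("RICS")),
               rep(0, nrow(m$vertices)))
  Tt <- rigid_transform("RICS", "RICS", translation = c(0, 4, 0))
  expect_equal(model_to_model_distance(m, Tt), rep(4, nrow(m$vertices)))
  ## pure rotation: distance equals |(R - I) v| per vertex
  Tr <- rigid_transform("RICS", "RICS", rotation = c(0, 0, 0.1))
  d <- model_to_model_distance(m, Tr)
  expected <- sqrt(rowSums((m$vertices %*% t(rotation_of(Tr) - diag(3)))^2))
  expect_equal(d, expected, tolerance = 1e-12)
})

test_that("one-way ANOVA reproduces hand-computed F and its invariances", {
  ## SSB = 4, SSW = 1, df (1, 2) -> F = 8
  out <- anova_oneway(list(c(1, 2), c(3, 4)))
  expect_equal(out$F, 8)
  expect_equal(out$df, c(1, 2))
  expect_equal(out$p, 1 - pf(8, 1, 2), tolerance = 1e-12)
  ## identical groups: F defined as 0, p = 1
  out0 <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_equal(out0$F, 0)
  expect_equal(out0$p, 1)
  ## location invariance
  g <- list(rnorm(5), rnorm(5) + 0.3, rnorm(5))
  a1 <- anova_oneway(g)
  a2 <- anova_oneway(lapply(g, `+`, 100))
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_error(anova_oneway(list(1:3)), "length")
})
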