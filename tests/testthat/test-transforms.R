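test_that("composition follows the apply-right-then-left convention", {
  Trot <- rigid_transform("WORLD", "HMD", rotation = c(0, 0, pi / 2))
  Ttra <- rigid_transform("HMD", "VCS", translation = c(1, 0, 0))
  Tc <- compose(Trot, Ttra)
  ## rotate (1,0,0) about z to (0,1,0), then translate by (1,0,0)
  expect_equal(apply_transform(Tc, c(1, 0, 0)), c(1, 1, 0), tolerance = 1e-12)
  expect_identical(c(Tc$source, Tc$target), c("WORLD", "VCS"))
  ## identity is neutral on either side
  expect_equal(compose(identity_transform("WORLD"), Trot)$matrix,
               Trot$matrix, tolerance = 1e-15)
  expect_equal(compose(Trot, invert(Trot))$matrix, diag(4),
               tolerance = 1e-12)
  expect_error(compose(Ttra, Trot), "frame mismatch")
})

test_that("inversion swaps frames and is an involution", {
  Tt <- rigid_transform("RICS", "SCS", translation = c(3, -2, 5))
  Ti <- invert(Tt)
  expect_equal(translation_of(Ti), c(-3, 2, -5))
  expect_identical(c(Ti$source, Ti$target), c("SCS", "RICS"))
  set.seed(42)
  for (k in 1:5) {
    Tr <- random_rigid_transform("WORLD", "HMD")
    expect_equal(invert(invert(Tr))$matrix, Tr$matrix, tolerance = 1e-12)
    ## rigidity preserved under inversion
    R <- rotation_of(invert(Tr))
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("apply_transform matches hand-computed rotations and preserves distances", {
  expect_equal(apply_transform(identity_transform("WORLD"), c(1, 2, 3)),
               c(1, 2, 3))
  Tz <- rigid_transform("WORLD", "WORLD", translation = c(0, 0, 10))
  expect_equal(apply_transform(Tz, c(0, 0, 0)), c(0, 0, 10))
  Tx <- rigid_transform("WORLD", "WORLD", rotation = c(pi, 0, 0))
  expect_equal(apply_transform(Tx, c(0, 1, 1)), c(0, -1, -1),
               tolerance = 1e-12)
  set.seed(3)
  P <- matrix(rnorm(30, sd = 50), 10, 3)
  Tr <- random_rigid_transform("WORLD", "HMD")
  Q <- apply_transform(Tr, P)
  expect_equal(as.vector(dist(P)), as.vector(dist(Q)), tolerance = 1e-9)
  expect_error(apply_transform(Tr, c(1, NA, 3)), "non-finite")
})

test_that("composition is associative on random seeded inputs", {
  set.seed(11)
  for (k in 1:20) {
    A <- random_rigid_transform("WORLD", "HMD")
    B <- random_rigid_transform("HMD", "VCS")
    C <- random_rigid_transform("VCS", "RICS")
    M1 <- compose(compose(A, B), C)$matrix
    M2 <- compose(A, compose(B, C))$matrix
    expect_lt(max(abs(M1 - M2)), 1e-9)
  }
})

test_that("constructors repair near-orthogonal rotations and reject bad ones", {
  R <- rotvec_to_matrix(c(0.2, -0.1, 0.3))
  Rn <- R + matrix(1e-8, 3, 3)
  Tr <- rigid_transform("WORLD", "HMD", rotation = Rn)
  expect_equal(crossprod(rotation_of(Tr)), diag(3), tolerance = 1e-12)
  expect_error(rigid_transform("WORLD", "HMD", rotation = R + 0.1),
               "not orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform("WORLD", "HMD", rotation = refl), "det")
  expect_error(rigid_transform("WORLD", "NOPE"), "unknown frame label")
})

test_that("rotation vector round-trips through the matrix form", {
  set.seed(5)
  for (k in 1:20) {
    rv <- rnorm(3) * runif(1, 0, 1)
    expect_equal(matrix_to_rotvec(rotvec_to_matrix(rv)), rv,
                 tolerance = 1e-9)
  }
  expect_equal(rotvec_to_matrix(c(0, 0, 0)), diag(3))
})

test_that("frame graph queries reversed pairs as inverses and names missing edges", {
  T_WH <- rigid_transform("WORLD", "HMD", rotation = c(0.1, 0.2, 0.3),
                          translation = c(5, 6, 7))
  g <- frame_graph(T_WH)
  expect_equal(get_edge(g, "HMD", "WORLD")$matrix, invert(T_WH)$matrix,
               tolerance = 1e-12)
  expect_error(get_edge(g, "VCS", "RICS"), "no transform")
  expect_error(chain_world_to_scanner(g), "T_HV")
})

test_that("the five-factor chain equals stepwise composition and sequential application", {
  set.seed(20231107)
  T_WH <- random_rigid_transform("WORLD", "HMD")
  T_HV <- random_rigid_transform("HMD", "VCS")
  T_VR <- random_rigid_transform("VCS", "RICS")
  T_RS <- random_rigid_transform("RICS", "SCS")
  T_SSc <- random_rigid_transform("SCS", "SCANNER")
  g <- frame_graph(T_WH, T_HV, T_VR, T_RS, T_SSc)
  Tc <- chain_world_to_scanner(g)
  ## stepwise: T_WV = T_HV.T_WH ; T_WS = T_VS.T_WV with T_VS = T_RS.T_VR
  T_WV <- compose(T_WH, T_HV)
  T_VS <- compose(T_VR, T_RS)
  T_WS <- compose(T_WV, T_VS)
  T_WSc <- compose(T_WS, T_SSc)
  expect_lt(max(abs(Tc$matrix - T_WSc$matrix)), 1e-9)
  ## sequential application oracle on points
  P <- matrix(rnorm(300, sd = 100), 100, 3)
  Q <- apply_transform(T_SSc, apply_transform(T_RS, apply_transform(
    T_VR, apply_transform(T_HV, apply_transform(T_WH, P)))))
  expect_lt(max(abs(apply_transform(Tc, P) - Q)), 1e-9)
  ## all-identity chain
  gi <- frame_graph(rigid_transform("WORLD", "HMD"),
                    rigid_transform("HMD", "VCS"),
                    rigid_transform("VCS", "RICS"),
                    rigid_transform("RICS", "SCS"),
                    rigid_transform("SCS", "SCANNER"))
  expect_equal(chain_world_to_scanner(gi)$matrix, diag(4))
})

test_that("transforms serialize to JSON and back bit-stably", {
  Tr <- rigid_transform("VCS", "RICS", rotation = c(0.3, -0.2, 0.1),
                        translation = c(5.25, -6.5, 7.125))
  T2 <- transform_from_json(transform_to_json(Tr))
  expect_identical(T2$matrix, Tr$matrix)
  expect_identical(c(T2$source, T2$target), c("VCS", "RICS"))
  p <- tempfile(fileext = ".json")
  transform_to_json(Tr, p)
  expect_identical(transform_from_json(p)$matrix, Tr$matrix)
})
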