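test_that("a nominal rig spans three orthogonal planes through one point", {
  rig <- build_rig()
  expect_true(rig$intrinsic_ok)
  expect_lt(rig_orthogonality_deviation(rig), 1e-12)
  ## fan planes contain their emitter boresight
  for (k in 1:4) {
    em <- rig$emitters[[crosshairsim:::FAN_TABLE$emitter[k]]]
    expect_lt(abs(sum(rig$fans[k, ] * em$boresight)), 1e-9)
  }
  ## distinct planes collapse to three; normals form a right-handed triad
  df <- crosshairsim:::rig_distinct_fans(rig)
  expect_equal(nrow(df$normals), 3L)
  expect_equal(det(df$normals), 1, tolerance = 1e-12)
})

test_that("fan perturbations break orthogonality by the stated angle", {
  rig <- build_rig(perturbation = c(2 * pi / 180, 0, 0, 0))
  expect_false(rig$intrinsic_ok)
  expect_equal(rig_orthogonality_deviation(rig) * 180 / pi, 2,
               tolerance = 1e-9)
  expect_error(build_rig(perturbation = c(0.3, 0, 0, 0)))
})

test_that("rig pose moves the SCS origin rigidly", {
  pose <- rigid_transform("SCS", "WORLD", translation = c(10, -5, 3))
  rig <- build_rig(pose = pose)
  expect_equal(apply_transform(rig$pose, c(0, 0, 0)), c(10, -5, 3))
})

test_that("crosshair projection on a sphere gives analytic circles", {
  sph <- sphere_mesh(60)
  rig <- build_rig()
  ## plane through the centre: great circle radius 60
  pc <- project_crosshair(rig, sph, 0.5)
  for (lb in c("sagittal", "coronal", "axial")) {
    for (cp in pc$curves[[lb]]) {
      n <- diag(3)[crosshairsim:::PLANE_ROLES[[lb]], ]
      expect_lt(max(abs(cp$points %*% n)), 1e-6)
      expect_lt(max(abs(sqrt(rowSums(cp$points^2)) - 60)), 0.05)
    }
  }
  ## offset plane: chord circle radius sqrt(R^2 - d^2)
  d <- 60 / sqrt(2)
  pose <- rigid_transform("SCS", "WORLD", translation = c(-d, 0, 0))
  pc2 <- project_crosshair(set_rig_pose(rig, pose), sph, 0.5)
  r_exp <- sqrt(60^2 - d^2)
  for (cp in pc2$curves$sagittal) {
    rho <- sqrt(cp$points[, 2]^2 + cp$points[, 3]^2)
    ## chord error of the ~4 mm triangulation at this oblique circle
    expect_lt(max(abs(rho - r_exp)), 0.1)
  }
  ## perturbed rig refuses to project until calibrated
  expect_error(project_crosshair(build_rig(perturbation = c(0.01, 0, 0, 0)),
                                 sph), "calibrated")
})

test_that("projection curves stay on a parabolic surface and its plane", {
  par40 <- make_parabolic_surface(40, 80)
  rig <- build_rig()
  pc <- project_crosshair(rig, par40, 0.5)
  for (cp in pc$curves$sagittal) {
    P <- cp$points
    expect_lt(max(abs(P[, 1])), 1e-6)
    expect_lt(max(abs(P[, 3] - (P[, 1]^2 + P[, 2]^2) / 80)), 0.05)
  }
})

test_that("curve misfit is symmetric, zero on identity, offset-faithful on a plate", {
  plate <- plate_mesh(60, 4)
  rig <- build_rig()
  a <- project_crosshair(rig, plate, 0.5)
  expect_equal(curve_misfit(a, a, labels = c("sagittal", "coronal")), 0,
               tolerance = 1e-12)
  ## translate the rig 2 mm along the sagittal plane normal: the projected
  ## sagittal line shifts by exactly 2 mm on the flat patch
  pose2 <- rigid_transform("SCS", "WORLD", translation = c(2, 0, 0))
  b <- project_crosshair(set_rig_pose(rig, pose2), plate, 0.5)
  m_ab <- curve_misfit(a, b, labels = "sagittal")
  expect_equal(m_ab, 2, tolerance = 0.05)
  expect_equal(curve_misfit(b, a, labels = "sagittal"), m_ab,
               tolerance = 1e-9)
  expect_error(curve_misfit(a, b, labels = "nonexistent"), "missing")
})

test_that("projection distortion decreases with curvature radius and scales with tilt", {
  tab <- curvature_sensitivity(c(40, 120), tilt = 1 * pi / 180)
  expect_equal(tab$radius_mm, c(40, 120))
  expect_gt(tab$misfit_mm[1], tab$misfit_mm[2])
  ## zero tilt: no distortion anywhere
  tab0 <- curvature_sensitivity(c(40, 120), tilt = 0)
  expect_lt(max(tab0$misfit_mm), 1e-9)
  ## first-order in tilt: halving the tilt roughly halves the misfit
  t1 <- curvature_sensitivity(60, tilt = 1 * pi / 180)$misfit_mm
  t2 <- curvature_sensitivity(60, tilt = 0.5 * pi / 180)$misfit_mm
  expect_equal(t1 / t2, 2, tolerance = 0.2)
})

test_that("rigs serialize to JSON and back", {
  pose <- rigid_transform("SCS", "WORLD", rotation = c(0.1, 0, -0.05),
                          translation = c(3, 4, 5))
  rig <- build_rig(perturbation = c(0.01, -0.02, 0, 0.005), pose = pose)
  rig2 <- rig_from_json(rig_to_json(rig))
  expect_identical(rig2$fans, rig$fans)
  expect_identical(rig2$pose$matrix, rig$pose$matrix)
  expect_false(rig2$intrinsic_ok)
})
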