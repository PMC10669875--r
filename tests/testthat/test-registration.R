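test_that("deployment from the true pose returns it with negligible misfit", {
  fx <- make_fixture(seed = 42)
  truth <- scs_pose_from_scanner(fx$scanner_pose)
  dep <- deploy_simulator(fx$marked_lines, fx$mesh, fx$rig, truth,
                          opts = list(n_starts = 1L))
  pd <- pose_difference(dep$pose, truth)
  expect_lt(pd$translation_mm, 0.1)
  expect_lt(pd$rotation_deg, 0.1)
  expect_lt(dep$misfit, 0.05)
  ## perfect alignment convention: simulator reproduces the scanner frame
  expect_equal(dep$t_ssc$matrix, diag(4))
  expect_identical(c(dep$t_ssc$source, dep$t_ssc$target),
                   c("SCS", "SCANNER"))
})

test_that("a single crosshair on a flat plate leaves the boresight unconstrained", {
  plate <- plate_mesh(60, 5)
  rig <- build_rig()
  pose <- rigid_transform("SCS", "WORLD")
  pc <- project_crosshair(set_rig_pose(rig, pose), plate, 0.5)
  ## only the top crosshair (sagittal + coronal) is visible on the plate
  expect_true(pc$empty[["axial"]])
  I6 <- deployment_information(pc, plate, rig, pose,
                               labels = c("sagittal", "coronal"))
  ev <- eigen(I6, symmetric = TRUE)$values
  ## translation along the top emitter boresight (z) is a null direction
  ez <- c(0, 0, 0, 0, 0, 1)
  expect_lt(abs(t(ez) %*% I6 %*% ez), 1e-9)
  ## in-plane translations and in-plane rotation are constrained
  expect_gt(t(c(0, 0, 0, 1, 0, 0)) %*% I6 %*% c(0, 0, 0, 1, 0, 0), 1)
  expect_gt(t(c(0, 0, 0, 0, 1, 0)) %*% I6 %*% c(0, 0, 0, 0, 1, 0), 1)
  expect_gt(t(c(0, 0, 1, 0, 0, 0)) %*% I6 %*% c(0, 0, 1, 0, 0, 0), 1)
  expect_lt(sum(ev > 1e-6 * max(ev)), 6L)
})

test_that("on a curved head all six degrees of freedom are constrained", {
  fx <- make_fixture(seed = 5)
  truth <- scs_pose_from_scanner(fx$scanner_pose)
  I6 <- deployment_information(fx$marked_lines, fx$mesh, fx$rig, truth)
  ev <- eigen(I6, symmetric = TRUE)$values
  ## weakest direction is still solidly constrained, unlike the exact
  ## null directions of the flat-plate case
  expect_gt(min(ev), 1)
  expect_gt(min(ev), 1e-7 * max(ev))
})

test_that("hologram registration maps model points through the chain exactly", {
  fx <- make_fixture(seed = 42)
  ## identity chain: points unchanged
  gi <- frame_graph(rigid_transform("WORLD", "HMD"),
                    rigid_transform("HMD", "VCS"),
                    rigid_transform("VCS", "RICS"),
                    rigid_transform("RICS", "SCS"),
                    rigid_transform("SCS", "SCANNER"))
  P <- matrix(rnorm(18, sd = 40), 6, 3)
  expect_equal(register_holograms(gi, P), P, tolerance = 1e-12)
  ## consistent fixture chain: mapped fiducials equal physical fiducials
  mapped <- register_holograms(fx$graph, fx$fiducials_rics$points)
  expect_lt(max(abs(mapped - fx$fiducials$points)), 1e-6)
  ## a 3 mm translation injected into the SCS-to-scanner link moves every
  ## mapped point by exactly 3 mm
  g2 <- add_edge(fx$graph, rigid_transform("SCS", "SCANNER",
                                           translation = c(3, 0, 0)))
  mapped2 <- register_holograms(g2, fx$fiducials_rics$points)
  shift <- sqrt(rowSums((mapped2 - mapped)^2))
  expect_equal(unname(shift), rep(3, nrow(mapped)), tolerance = 1e-9)
})

test_that("freeze snapshots, drift accumulates, unfreeze discards drift", {
  live <- rigid_transform("RICS", "WORLD", translation = c(1, 2, 3))
  st <- registration_state(live, drift_sigma = 0.05, seed = 3)
  expect_equal(current_transform(st)$matrix, live$matrix)
  st <- freeze(st)
  expect_identical(current_transform(st)$matrix, live$matrix)
  st <- step_drift(st, 100L)
  expect_gt(sqrt(sum((translation_of(current_transform(st)) -
                        translation_of(live))^2)), 0)
  st <- unfreeze(st)
  expect_identical(current_transform(st)$matrix, live$matrix)
  ## without a drift model the frozen transform is constant
  st2 <- freeze(registration_state(live))
  st2 <- step_drift(st2, 100L)
  expect_identical(current_transform(st2)$matrix, live$matrix)
})

test_that("drift displacement follows the random-walk RMS sigma*sqrt(3n)", {
  sigma <- 0.05; n <- 50L; reps <- 400L
  live <- rigid_transform("RICS", "WORLD")
  disp2 <- vapply(seq_len(reps), function(r) {
    st <- freeze(registration_state(live, drift_sigma = sigma, seed = r))
    st <- step_drift(st, n)
    sum((translation_of(current_transform(st)))^2)
  }, 0)
  expect_equal(sqrt(mean(disp2)), sigma * sqrt(3 * n), tolerance = 0.1)
})
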