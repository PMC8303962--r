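test_that("3-D MSE matches the nested-loop oracle and handles masks", {
  set.seed(61)
  a <- new_volume(array(rnorm(5^3), c(5, 5, 5)))
  b <- new_volume(array(rnorm(5^3), c(5, 5, 5)))
  expect_equal(mse_3d(a, b, mask = "full"), mse_oracle(a$voxels, b$voxels),
               tolerance = 1e-12)
  expect_equal(mse_3d(a, a), 0)
  cc <- new_volume(a$voxels + 4, a$spacing, a$origin)
  expect_equal(mse_3d(a, cc), 16, tolerance = 1e-12)
  # explicit logical mask and the empty-overlap error
  m <- array(FALSE, c(5, 5, 5)); m[1:2, , ] <- TRUE
  expect_equal(mse_3d(a, b, mask = m),
               mean((a$voxels[1:2, , ] - b$voxels[1:2, , ])^2), tolerance = 1e-12)
  expect_error(mse_3d(a, b, mask = array(FALSE, c(5, 5, 5))), "no overlap")
})

test_that("the gradient vanishes at the optimum and points downhill", {
  blob <- make_smooth_blob(n = 32, extent = 64)
  g0 <- mse_gradient(blob, blob, pose6())
  expect_lt(max(abs(g0)), 1e-6)
  # pure +x misalignment of an x-varying phantom: tx dominates, sign downhill
  fx <- pseudo_reconstruct(blob, pose6(tx = 3), 0, 0, 1)
  g <- mse_gradient(blob, fx, pose6())
  expect_gt(abs(g[4]), 5 * max(abs(g[c(5, 6)])))
  # moving along -gradient must decrease the MSE
  ctr <- volume_center(blob)
  m0 <- attr(g, "mse")
  stepped <- pose6(tx = -0.5 * sign(g[4]))
  expect_lt(orthoreg:::pose_mse(blob, fx, stepped, ctr), m0)
})

test_that("registering to a clean transformed copy recovers the pose", {
  ph <- make_phantom(seed = 77)
  moving <- preprocess_ct(ph$volume)$volume
  ctr <- volume_center(moving)
  pose_gt <- pose_from_degrees(4, -6, 3, 8, -12, 5)
  fixed <- pseudo_reconstruct(moving, pose_gt, 0, 0, 1)
  res <- register_volumes(moving, fixed)
  err <- pose_errors(res$pose, pose_gt, center = ctr)
  expect_lt(max(err[1:3]), 0.5)
  expect_lt(max(err[4:6]), 0.5)
  expect_true(res$converged)
  expect_lte(res$mse, res$initial_mse)
  # trivial self-registration terminates at once with zero MSE
  self <- register_volumes(moving, moving)
  expect_equal(unclass(self$pose), unclass(pose6()), tolerance = 1e-9)
  expect_equal(self$mse, 0)
})

test_that("accepted iterates decrease the MSE monotonically within each level", {
  blob <- make_smooth_blob(n = 32, extent = 64)
  fx <- pseudo_reconstruct(blob, pose_from_degrees(3, -2, 4, 5, -6, 2), 0, 0, 1)
  res <- register_volumes(blob, fx,
                          config = registration_config(init_search = FALSE))
  for (lev in unique(res$trajectory$level)) {
    mses <- res$trajectory$mse[res$trajectory$level == lev]
    expect_true(all(diff(mses) <= 0))
  }
})

test_that("forward and backward registrations compose to the identity", {
  ph <- make_phantom(seed = 78)
  vol <- preprocess_ct(ph$volume)$volume
  ctr <- volume_center(vol)
  pose_gt <- pose_from_degrees(5, 3, -4, -6, 9, 4)
  fixed <- pseudo_reconstruct(vol, pose_gt, 0, 0, 1)
  fwd <- register_volumes(vol, fixed)
  bwd <- register_volumes(fixed, vol)
  comp <- compose(pose_to_matrix(bwd$pose, ctr), pose_to_matrix(fwd$pose, ctr))
  resid <- matrix_to_pose(comp, center = ctr)
  expect_lt(max(abs(resid[1:3])) / (pi / 180), 0.75)
  expect_lt(max(abs(resid[4:6])), 0.75)
})

test_that("metric and gradient are pure maps: chunked evaluation agrees", {
  set.seed(67)
  blob <- make_smooth_blob(n = 24, extent = 48)
  fx <- pseudo_reconstruct(blob, pose6(tx = 2, alpha = 0.03), 0, 0, 1)
  p <- pose_from_degrees(1, -1, 2, 1, 0, -1)
  ctr <- volume_center(blob)
  whole <- orthoreg:::pose_mse(blob, fx, p, ctr, mask = "full")
  # recompute as a chunked sum over the fixed grid
  pts <- voxel_world_coords(fx)
  q <- apply_points(invert_transform(pose_to_matrix(p, ctr)), pts)
  idx <- split(seq_len(nrow(q)), rep(1:5, length.out = nrow(q)))
  tot <- 0
  for (ch in idx) {
    vals <- as.numeric(sample_trilinear(blob, q[ch, , drop = FALSE]))
    tot <- tot + sum((vals - as.vector(fx$voxels)[ch])^2)
  }
  expect_equal(tot / nrow(q), whole, tolerance = 1e-9)
})

test_that("registered volume reproduces the fixed volume's biplanar DRRs", {
  ph <- make_phantom(seed = 79)
  vol <- preprocess_ct(ph$volume)$volume
  ctr <- volume_center(vol)
  pose_gt <- pose_from_degrees(-5, 4, 6, 10, -8, 6)
  fixed <- pseudo_reconstruct(vol, pose_gt, 0, 0, 1)
  res <- register_volumes(vol, fixed)
  geom <- projection_geometry(detector_px = c(32, 32), pixel_spacing = c(6, 6),
                              isocenter = ctr)
  drr_fixed <- render_biplanar(fixed, pose6(), geom)
  drr_init <- render_biplanar(vol, pose6(), geom)
  drr_reg <- render_biplanar(vol, res$pose, geom)
  mse2d <- function(a, b) mean((a$pixels - b$pixels)^2)
  expect_lt(mse2d(drr_reg$ap, drr_fixed$ap), mse2d(drr_init$ap, drr_fixed$ap))
  expect_lt(mse2d(drr_reg$lat, drr_fixed$lat), mse2d(drr_init$lat, drr_fixed$lat))
})

test_that("registration errors and config validation are explicit", {
  a <- new_volume(array(1, c(8, 8, 8)), c(1, 1, 1), c(0, 0, 0))
  far <- new_volume(array(1, c(8, 8, 8)), c(1, 1, 1), c(1000, 1000, 1000))
  expect_error(mse_gradient(a, far, pose6()), "no overlap")
  expect_error(registration_config(backtrack = 1.5), "positive")
  expect_error(registration_config(pyramid = c(2, 4, 1)), "descending")
  expect_error(registration_config(pyramid = c(4, 2)), "ending at 1")
})

test_that("tidy and glance expose the trajectory and summary", {
  blob <- make_smooth_blob(n = 24, extent = 48)
  fx <- pseudo_reconstruct(blob, pose6(tx = 2), 0, 0, 1)
  res <- register_volumes(blob, fx)
  td <- tidy(res)
  expect_true(all(c("level", "iter", "alpha_deg", "tx", "mse") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$final_mse, res$mse)
  expect_true(gl$converged)
})
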