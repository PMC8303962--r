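test_that("the head phantom is deterministic per seed with valid landmarks", {
  a <- make_phantom(seed = 5)
  b <- make_phantom(seed = 5)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$landmarks$coords, b$landmarks$coords)
  c2 <- make_phantom(seed = 6)
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
  expect_equal(nrow(a$landmarks$coords), 12)
  expect_error(make_phantom(seed = 1, shape = c(16, 64, 64)), "at least 32")
})

test_that("canal landmarks sit in low-HU canals surrounded by bone", {
  ph <- make_phantom(seed = 9, noise_sd = 0)
  vol <- ph$volume
  for (j in 1:2) {
    lm <- ph$landmarks$coords[j, ]
    hu <- as.numeric(sample_trilinear(vol, lm))
    expect_lt(hu, 100)                       # inside the carved canal
    # some close neighbor in the skull base plane is shell bone
    ring <- lm + rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
    ring_hu <- as.numeric(sample_trilinear(vol, ring))
    expect_gt(max(ring_hu), 100)
  }
  # the ten extra landmarks lie on shell bone
  extra_hu <- as.numeric(sample_trilinear(vol, ph$landmarks$coords[3:12, ]))
  expect_true(all(extra_hu >= 100))
})

test_that("the thresholded phantom retains one connected bone component", {
  ph <- make_phantom(seed = 10)
  bone <- threshold_bone(ph$volume)$voxels > 0
  expect_gt(sum(bone), 1000)
  seed_idx <- which(bone, arr.ind = TRUE)[1, ]
  grown <- connected_from_seed(bone, seed_idx)
  expect_identical(grown, bone)              # all bone voxels are 6-connected
})

test_that("pose sampling respects the benchmark ranges and is unbiased", {
  draws <- t(vapply(1:10000, function(s) unclass(sample_pose(s)), numeric(6)))
  expect_true(all(abs(draws[, 1:3]) < 10 * pi / 180))
  expect_true(all(abs(draws[, 4:6]) < 20))
  # means within 3 standard errors of zero for each component
  se_rot <- (20 * pi / 180) / sqrt(12) / sqrt(10000)
  se_tr <- 40 / sqrt(12) / sqrt(10000)
  expect_true(all(abs(colMeans(draws[, 1:3])) < 3 * se_rot))
  expect_true(all(abs(colMeans(draws[, 4:6])) < 3 * se_tr))
  expect_identical(unclass(sample_pose(123)), unclass(sample_pose(123)))
})

test_that("extreme poses sit at the corners of the range", {
  p <- extreme_pose(rep(1, 6))
  expect_equal(unclass(p),
               unclass(pose_from_degrees(10, 10, 10, 20, 20, 20)))
  expect_equal(unclass(extreme_pose(rep(-1, 6))), -unclass(p))
  expect_equal(sqrt(sum(unclass(p)[4:6]^2)), 20 * sqrt(3))
  expect_error(extreme_pose(c(1, 1, 1, 1, 1, 2)), "\\+1 or -1")
})

test_that("benchmark cases store exact ground truth and reproduce bit-wise", {
  ph <- make_phantom(seed = 15, shape = c(32, 32, 32), spacing = c(3, 3, 3))
  vol <- threshold_bone(ph$volume)
  geom <- projection_geometry(detector_px = c(16, 16), pixel_spacing = c(8, 8),
                              isocenter = volume_center(vol))
  pose <- sample_pose(42)
  c1 <- generate_case(vol, ph$landmarks, pose, geometry = geom, seed = 42)
  c2 <- generate_case(vol, ph$landmarks, pose, geometry = geom, seed = 42)
  expect_identical(unclass(c1$pose_gt), unclass(pose))
  expect_identical(c1$drr_ap_raw$pixels, c2$drr_ap_raw$pixels)
  expect_identical(c1$drr_lat_raw$pixels, c2$drr_lat_raw$pixels)
})

test_that("a symmetric phantom at identity pose yields equal AP and LAT", {
  n <- 33
  x <- seq(-16, 16, length.out = n)
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  sph <- new_volume(array(200 * exp(-r2 / 60), c(n, n, n)), c(1, 1, 1),
                    c(-16, -16, -16))
  lm <- landmark_set(rbind(c(0, 0, 0), c(1, 1, 1)))
  geom <- projection_geometry(detector_px = c(17, 17), pixel_spacing = c(2, 2),
                              isocenter = c(0, 0, 0))
  case <- generate_case(sph, lm, pose6(), angle_deg = 90, geometry = geom)
  expect_lt(max(abs(case$drr_ap_raw$pixels - case$drr_lat_raw$pixels)), 1e-6)
})

test_that("pseudo-reconstruction degrades as configured", {
  ph <- make_phantom(seed = 21, shape = c(32, 32, 32), spacing = c(3, 3, 3))
  vol <- threshold_bone(ph$volume)
  pose <- pose_from_degrees(2, -3, 1, 5, 4, -6)
  # degenerate parameters give exactly the clean transformed copy
  clean <- resample_rigid(vol, pose_to_matrix(pose, volume_center(vol)))
  degen <- pseudo_reconstruct(vol, pose, 0, 0, 1)
  expect_identical(degen$voxels, clean$voxels)
  # additive noise has the requested amplitude (5% of dynamic range)
  noisy <- pseudo_reconstruct(vol, pose, 0, 0.05, 1, seed = 8)
  resid_sd <- sd(noisy$voxels - clean$voxels)
  want <- 0.05 * diff(range(clean$voxels))
  expect_lt(abs(resid_sd - want) / want, 0.1)
  expect_identical(pseudo_reconstruct(vol, pose, 1, 0.05, 1, seed = 8)$voxels,
                   pseudo_reconstruct(vol, pose, 1, 0.05, 1, seed = 8)$voxels)
  expect_error(pseudo_reconstruct(vol, pose, -1, 0, 1), "non-negative")
})

test_that("view-angle degradation grows as views collapse", {
  d90 <- angle_degradation(90)
  d60 <- angle_degradation(60)
  d30 <- angle_degradation(30)
  expect_equal(d90$blur_sigma, 1)
  expect_equal(d30$blur_sigma, 2)
  expect_true(d90$noise_frac < d60$noise_frac)
  expect_true(d60$noise_frac < d30$noise_frac)
  expect_error(angle_degradation(0), "between 0 and 180")
})

test_that("dataset manifests split 75/25 exactly and reproducibly", {
  m <- build_dataset(40, seed = 3)
  expect_equal(sum(m$split == "train"), 30)
  expect_equal(sum(m$split == "test"), 10)
  expect_identical(sort(unique(m$split)), c("test", "train"))
  m2 <- build_dataset(40, seed = 3)
  expect_identical(m, m2)
  expect_false(identical(m$split, build_dataset(40, seed = 4)$split))
  # all sampled poses inside the declared ranges
  expect_true(all(abs(c(m$alpha_deg, m$beta_deg, m$gamma_deg)) < 10))
  expect_true(all(abs(c(m$tx_mm, m$ty_mm, m$tz_mm)) < 20))
  # JSONL round trip
  f <- tempfile(fileext = ".jsonl")
  write_manifest(m, f)
  got <- read_manifest(f)
  expect_equal(got$case_id, m$case_id)
  expect_equal(got$tx_mm, m$tx_mm, tolerance = 1e-12)
})
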