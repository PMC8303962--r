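test_that("DRR of a homogeneous cube matches analytic chord lengths", {
  cube <- new_volume(array(1, c(65, 65, 65)), c(1, 1, 1), c(-32, -32, -32))
  step <- 0.5
  geom <- projection_geometry(sid = 1000, sdd = 1500, detector_px = c(9, 9),
                              pixel_spacing = c(6, 6), step = step)
  d <- render_drr(cube, pose6(), geom, center = c(0, 0, 0))
  rays <- orthoreg:::geometry_rays(geom)
  want <- vapply(seq_len(nrow(rays$dst)), function(i)
    chord_oracle(rays$src, rays$dst[i, ], rep(-32, 3), rep(32, 3)), numeric(1))
  expect_lt(max(abs(as.vector(d$pixels) - want)), 2 * step)
})

test_that("ray-march quadrature converges first order in the step", {
  cube <- new_volume(array(1, c(33, 33, 33)), c(2, 2, 2), c(-32, -32, -32))
  g1 <- projection_geometry(detector_px = c(5, 5), pixel_spacing = c(8, 8), step = 1)
  g2 <- projection_geometry(detector_px = c(5, 5), pixel_spacing = c(8, 8), step = 0.5)
  d1 <- render_drr(cube, pose6(), g1, center = c(0, 0, 0))
  d2 <- render_drr(cube, pose6(), g2, center = c(0, 0, 0))
  expect_lt(max(abs(d1$pixels - d2$pixels)), 1)
})

test_that("rendering is linear in the volume and zero for empty scenes", {
  set.seed(47)
  vol <- new_volume(array(runif(16^3), c(16, 16, 16)), c(4, 4, 4), c(0, 0, 0))
  geom <- projection_geometry(detector_px = c(7, 7), pixel_spacing = c(10, 10),
                              isocenter = volume_center(vol))
  d1 <- render_drr(vol, pose6(), geom)
  d2 <- render_drr(new_volume(2 * vol$voxels, vol$spacing, vol$origin),
                   pose6(), geom)
  expect_equal(d2$pixels, 2 * d1$pixels, tolerance = 1e-9)
  zero <- new_volume(array(0, c(8, 8, 8)), c(4, 4, 4), c(0, 0, 0))
  dz <- render_drr(zero, pose6(), geom)
  expect_true(all(dz$pixels == 0))
})

test_that("a centered spherically symmetric phantom gives equal AP and LAT views", {
  n <- 33
  x <- seq(-16, 16, length.out = n)
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  sph <- new_volume(array(exp(-r2 / 50), c(n, n, n)), c(1, 1, 1),
                    c(-16, -16, -16))
  geom <- projection_geometry(detector_px = c(21, 21), pixel_spacing = c(2, 2),
                              isocenter = c(0, 0, 0))
  pair <- render_biplanar(sph, pose6(), geom)
  expect_lt(max(abs(pair$ap$pixels - pair$lat$pixels)), 1e-6)
})

test_that("off-center blobs project with the pinhole magnification", {
  bl <- new_volume(array(0, c(41, 41, 41)), c(1, 1, 1), c(-20, -20, -20))
  bl$voxels[21, 29, 21] <- 1000     # at world y = +8 mm, x = z = 0
  geom <- projection_geometry(sid = 1000, sdd = 1500, detector_px = c(81, 81),
                              pixel_spacing = c(1, 1), isocenter = c(0, 0, 0),
                              step = 0.25)
  d <- render_drr(bl, pose6(), geom, center = c(0, 0, 0))
  pk <- which(d$pixels == max(d$pixels), arr.ind = TRUE)
  # detector u = y * sdd / sid = 12 mm -> one pixel per mm from center 41
  expect_lt(max(abs(pk[1, ] - c(53, 41))), 1.5)
})

test_that("twice the 90-degree view transform equals the 180-degree view", {
  vol <- new_volume(array(0, c(41, 41, 41)), c(1, 1, 1), c(-20, -20, -20))
  vol$voxels[21, 25, 23] <- 500     # x-symmetric scene (single mid-depth blob)
  base <- projection_geometry(detector_px = c(21, 21), pixel_spacing = c(2, 2),
                              step = 0.25)
  g180 <- base
  g180$view_transform <- compose(lat_view_transform(90), lat_view_transform(90))
  dAP <- render_drr(vol, pose6(), base, center = c(0, 0, 0))
  d180 <- render_drr(vol, pose6(), g180, center = c(0, 0, 0))
  # opposite view of a depth-centered scene: the u axis is mirrored
  expect_lt(max(abs(d180$pixels - dAP$pixels[rev(seq_len(21)), ])), 1e-6)
})

test_that("in-plane translation shifts the image by one pixel in the orthographic limit", {
  blob <- make_smooth_blob(n = 32, extent = 64)
  # unit magnification (detector plane through the isocenter, source far away)
  geom <- projection_geometry(sid = 1e6, sdd = 1e6 + 1, detector_px = c(33, 33),
                              pixel_spacing = c(2, 2),
                              isocenter = volume_center(blob), step = 1)
  d0 <- render_drr(blob, pose6(), geom)
  d1 <- render_drr(blob, pose6(ty = 2), geom)   # one detector pixel (2 mm)
  expect_lt(max(abs(d1$pixels[2:33, ] - d0$pixels[1:32, ])),
            0.02 * max(d0$pixels))
})

test_that("supervision losses match direct arithmetic", {
  a <- new_volume(array(rnorm(4^3), c(4, 4, 4)))
  expect_equal(reconstruction_loss(a, a), 0)
  b <- new_volume(a$voxels + 3, a$spacing, a$origin)
  expect_equal(reconstruction_loss(a, b), 9, tolerance = 1e-12)
  set.seed(53)
  c2 <- new_volume(array(rnorm(4^3), c(4, 4, 4)))
  expect_equal(reconstruction_loss(a, c2), mse_oracle(a$voxels, c2$voxels),
               tolerance = 1e-12)

  zv <- new_volume(array(0, c(8, 8, 8)), c(4, 4, 4), c(0, 0, 0))
  gsm <- projection_geometry(detector_px = c(4, 4), pixel_spacing = c(8, 8),
                             isocenter = volume_center(zv))
  ones <- drr_image(matrix(1, 4, 4))
  expect_equal(perspective_projection_loss(zv, ones, ones, gsm), 1)
  # a volume's own renders as targets give zero loss
  blob <- make_smooth_blob(n = 16, extent = 32)
  gb <- projection_geometry(detector_px = c(6, 6), pixel_spacing = c(8, 8),
                            isocenter = volume_center(blob))
  own <- render_biplanar(blob, pose6(), gb)
  expect_equal(perspective_projection_loss(blob, own$ap, own$lat, gb), 0)
  # two-pixel worked example: mean over both views of squared differences
  t_ap <- drr_image(matrix(c(1, 3), 1, 2)); t_lat <- drr_image(matrix(c(2, 2), 1, 2))
  g2 <- projection_geometry(detector_px = c(1, 2), pixel_spacing = c(8, 8),
                            isocenter = volume_center(zv))
  r0 <- render_biplanar(zv, pose6(), g2)
  want <- 0.5 * (mean((t_ap$pixels - r0$ap$pixels)^2) +
                   mean((t_lat$pixels - r0$lat$pixels)^2))
  expect_equal(perspective_projection_loss(zv, t_ap, t_lat, g2), want)
  expect_equal(want, 0.5 * (mean(c(1, 9)) + mean(c(4, 4))))
})

test_that("the weighted generator loss combines terms as specified", {
  expect_equal(total_generator_loss(1, 1, 1), 20.1)
  expect_equal(total_generator_loss(0, 0, 0), 0)
  expect_equal(total_generator_loss(2, 4, 6, eps = c(0.1, 10, 10)),
               2 * total_generator_loss(1, 2, 3))
})

test_that("contrast variants are monotone with mid as the identity", {
  set.seed(59)
  img <- drr_image(matrix(runif(100, 0, 7), 10, 10))
  mid <- contrast_adjust(img, "mid")
  nrm <- (img$pixels - min(img$pixels)) / diff(range(img$pixels))
  expect_equal(mid$pixels, nrm)
  for (lev in c("low", "high")) {
    out <- contrast_adjust(img, lev)
    expect_identical(order(out$pixels), order(img$pixels))
  }
  # three-level oracle: gamma < 1 compresses the upper range, so the two
  # brightest levels are closer (lower Michelson contrast) than under
  # gamma > 1
  tri <- drr_image(matrix(c(0, 0.25, 1), 1, 3))
  mich <- function(px) {
    two <- sort(px, decreasing = TRUE)[1:2]
    (two[1] - two[2]) / (two[1] + two[2])
  }
  m_low <- mich(contrast_adjust(tri, "low")$pixels)    # (1 - sqrt(.25))/(1 + sqrt(.25))
  m_high <- mich(contrast_adjust(tri, "high")$pixels)  # (1 - .25^2)/(1 + .25^2)
  expect_equal(m_low, (1 - 0.5) / (1 + 0.5))
  expect_equal(m_high, (1 - 0.0625) / (1 + 0.0625))
  expect_lt(m_low, m_high)
})

test_that("geometry validation rejects impossible setups", {
  expect_error(projection_geometry(sid = -1), "positive")
  expect_error(projection_geometry(sid = 1500, sdd = 1000), "beyond the isocenter")
  expect_error(projection_geometry(step = 0), "positive")
  expect_error(projection_geometry(detector_px = c(0, 4)), "positive integers")
})
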