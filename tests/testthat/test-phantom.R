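test_that("phantom generation is deterministic and honours the target gap", {
  cfg <- small_phantom_config(seed = 4L, noise_sigma_hu = 12)
  ph1 <- generatePhantom(cfg)
  ph2 <- generatePhantom(cfg)
  expect_identical(voxels(ph1@intraop), voxels(ph2@intraop))
  expect_identical(voxels(ph1@preop), voxels(ph2@preop))
  expect_equal(ph1@truth$gap_mm, cfg@target_gap_mm, tolerance = 1e-6)

  # measured maximum axial gap extent from the truth mask within one voxel
  g <- maxAirGapDistance(ph1@truth$air_gap, ph1@truth$pose, cfg@spec)
  expect_lt(abs(g - cfg@target_gap_mm), 1.5)
})

test_that("zero motion/gap/noise phantom differs from preop only at the cavity and applicator", {
  cfg <- small_phantom_config(motion_rot_deg = c(0, 0, 0),
                              motion_trans_mm = c(0, 0, 0),
                              target_gap_mm = 0, irregularity_mm = 0)
  ph <- generatePhantom(cfg)
  differ <- voxels(ph@intraop) != voxels(ph@preop)
  allowed <- voxels(ph@truth$cavity) | voxels(ph@truth$applicator_wall) |
    voxels(ph@truth$air_gap)
  expect_true(all(allowed[differ]))
})

test_that("the intraop body equals the moved preop body minus the cavity", {
  cfg <- small_phantom_config(seed = 9L)
  ph <- generatePhantom(cfg)
  moved_pre <- applyTransform(ph@preop, ph@truth$motion,
                              reference = ph@intraop)
  # threshold at the air/tissue midpoint: the unbiased surface estimate
  # under trilinear resampling
  moved <- bodyMask(moved_pre, threshold_hu = -480)
  moved_minus_cavity <- voxels(moved) & !voxels(ph@truth$cavity) &
    !voxels(ph@truth$air_gap)
  expect_gt(dice(moved_minus_cavity, voxels(ph@truth$body)), 0.99)
})

test_that("carveCavity: analytic cap depth, oracle match, idempotence", {
  v <- CTVolume(array(40, c(48, 48, 40)), spacing = c(1.5, 1.5, 1.5),
                origin = -c(47, 47, 39) * 1.5 / 2)
  # amplitude 0: spherical-cap floor, analytic centre depth
  cc <- carveCavity(v, centre = c(0, 0, 20), depth_mm = 12, amplitude_mm = 0,
                    radius_mm = 20)
  w <- voxelCentres(v)
  carved <- voxels(cc$mask)
  zmin_at_centre <- min(w[carved & sqrt(w[, 1]^2 + w[, 2]^2) < 1.5, 3])
  expect_lt(abs((20 - zmin_at_centre) - 12), 1.6)
  expect_equal(cc$floor_fun(0, 0), 20 - 12, tolerance = 1e-9)

  # amplitude 8: deepest carved voxel tracks the perturbed floor function
  cc8 <- carveCavity(v, centre = c(0, 0, 20), depth_mm = 12,
                     amplitude_mm = 8, seed = 31L, radius_mm = 20)
  grid <- expand.grid(x = seq(-20, 20, by = 0.2), y = seq(-20, 20, by = 0.2))
  fl <- cc8$floor_fun(grid$x, grid$y)
  oracle_max_depth <- 20 - min(fl)
  carved8 <- voxels(cc8$mask)
  measured <- 20 - min(w[carved8, 3])
  expect_lt(abs(measured - oracle_max_depth), 1.6)

  # idempotent mask under identical arguments
  cc_again <- carveCavity(cc8$volume, centre = c(0, 0, 20), depth_mm = 12,
                          amplitude_mm = 8, seed = 31L, radius_mm = 20)
  expect_identical(voxels(cc_again$mask), voxels(cc8$mask))
  expect_error(carveCavity(v, centre = c(30, 0, 20), depth_mm = 12,
                           radius_mm = 20), "bounds")
})

test_that("placeApplicator geometry: bevel plane, edge lengths, shell volume", {
  sp15 <- c(1.5, 1.5, 1.5)
  v <- CTVolume(array(-1000, c(80, 80, 100)), spacing = sp15,
                origin = -c(79, 79, 99) * 1.5 / 2)
  pose0 <- applicatorPose(c(0, 0, -40), c(0, 0, -1), roll_undefined = TRUE)

  # bevel 0: the distal rim lies in a single plane normal to the axis
  p0 <- placeApplicator(v, applicatorSpec(5, 0), pose0)
  w <- voxelCentres(v)[which(voxels(p0$mask)), ]
  rim_z <- tapply(-w[, 3], cut(atan2(w[, 2], w[, 1]), 24), max)
  expect_lt(diff(range(rim_z)), 1.6)

  # bevel 30, diameter 7 cm: axial distance between the longest and
  # shortest wall edge is 70 * tan(30 deg) ~ 40.4 mm (at the aperture radius)
  spec7 <- applicatorSpec(7, 30)
  pose7 <- applicatorPose(c(0, 0, -50), c(0, 0, -1), roll_deg = 0)
  p7 <- placeApplicator(v, spec7, pose7)
  w7 <- voxelCentres(v)[which(voxels(p7$mask)), ]
  rho <- sqrt(w7[, 1]^2 + w7[, 2]^2)
  inner_edge <- abs(rho - 35) < 1.5
  zmax_by_angle <- tapply(w7[inner_edge, 3],
                          cut(atan2(w7[inner_edge, 2], w7[inner_edge, 1]), 24),
                          min)
  expect_lt(abs(diff(range(zmax_by_angle)) - 70 * tan(30 * pi / 180)), 3)

  # wall voxel count approximates the analytic shell volume
  spec5 <- applicatorSpec(5, 0, length_mm = 60)
  p5 <- placeApplicator(v, spec5, applicatorPose(c(0, 0, -60), c(0, 0, -1),
                                                 roll_undefined = TRUE))
  analytic <- pi * (30^2 - 25^2) * 60
  expect_lt(abs(sum(voxels(p5$mask)) * prod(sp15) - analytic) / analytic, 0.1)

  expect_error(placeApplicator(v, spec5,
                               applicatorPose(c(500, 0, 0), c(0, 0, -1),
                                              roll_undefined = TRUE)),
               "does not intersect")
})

test_that("addNoise is seeded, unbiased and optional", {
  v <- CTVolume(array(0, c(30, 30, 30)))
  expect_identical(voxels(addNoise(v, 0)), voxels(v))
  n1 <- addNoise(v, 20, seed = 8L)
  n2 <- addNoise(v, 20, seed = 8L)
  expect_identical(voxels(n1), voxels(n2))
  expect_lt(abs(stats::sd(voxels(n1)) - 20) / 20, 0.05)
})

test_that("ground-truth air gap agrees with the segmentation module", {
  cfg <- small_phantom_config(seed = 6L)
  ph <- generatePhantom(cfg)
  gap <- segmentAirGap(ph@intraop, ph@truth$pose, cfg@spec)
  expect_gte(dice(gap, ph@truth$air_gap), 0.95)
})
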