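test_that("region growing matches a brute-force flood-fill oracle", {
  set.seed(21)
  d <- c(16, 16, 16)
  for (conn in c(6, 26)) {
    for (rep in 1:3) {
      vol <- CTVolume(array(rnorm(prod(d), 0, 200), d))
      inwin <- vol@values >= -100 & vol@values <= 250
      seeds <- which(inwin, arr.ind = TRUE)
      seeds <- seeds[seq(1, nrow(seeds), length.out = 3), , drop = FALSE]
      got <- regionGrow(vol, seeds, -100, 250, connectivity = conn)
      expect_identical(voxels(got), flood_oracle(inwin, seeds, conn))
    }
  }
})

test_that("region growing basics: full volume, barriers, seed errors", {
  v <- CTVolume(array(50, c(8, 8, 8)))
  m <- regionGrow(v, c(4, 4, 4), 0, 100)
  expect_true(all(voxels(m)))

  # a closed out-of-window shell confines growth
  arr <- array(50, c(11, 11, 11))
  arr[c(3, 9), 3:9, 3:9] <- 500
  arr[3:9, c(3, 9), 3:9] <- 500
  arr[3:9, 3:9, c(3, 9)] <- 500
  vs <- CTVolume(arr)
  inside <- regionGrow(vs, c(6, 6, 6), 0, 100)
  expect_true(all(which(voxels(inside), arr.ind = TRUE) >= 4 &
                  which(voxels(inside), arr.ind = TRUE) <= 8))
  expect_equal(sum(voxels(inside)), 5^3)

  expect_error(regionGrow(vs, c(3, 3, 3), 0, 100), "window")
  expect_error(regionGrow(vs, c(100, 1, 1), 0, 100), "outside")
})

test_that("region growing is seed-invariant within a component and monotone in the constraint", {
  cfg <- small_phantom_config(seed = 2L)
  ph <- generatePhantom(cfg)
  seeds_all <- which(voxels(ph@intraop) >= 500, arr.ind = TRUE)
  m1 <- regionGrow(ph@intraop, seeds_all[1, , drop = FALSE], 200, Inf)
  comp_of_seed <- voxels(m1)
  other <- seeds_all[comp_of_seed[seeds_all], , drop = FALSE]
  m2 <- regionGrow(ph@intraop, other[nrow(other), , drop = FALSE], 200, Inf)
  expect_identical(voxels(m2), comp_of_seed)

  # growing the constraint can only grow the result
  w <- voxelCentres(ph@intraop)
  small <- Mask(array(w[, 1] < 0, imgDim(ph@intraop)), like = ph@intraop)
  big <- Mask(array(w[, 1] < 20, imgDim(ph@intraop)), like = ph@intraop)
  seeds <- seeds_all[seeds_all[, 1] < imgDim(ph@intraop)[1] / 2, , drop = FALSE]
  gs <- regionGrow(ph@intraop, seeds[1, , drop = FALSE], 200, Inf, constraint = small)
  gb <- regionGrow(ph@intraop, seeds[1, , drop = FALSE], 200, Inf, constraint = big)
  expect_true(all(voxels(gb)[voxels(gs)]))
})

test_that("bone segmentation recovers the phantom bones", {
  cfg <- small_phantom_config(seed = 5L, noise_sigma_hu = 12)
  ph <- generatePhantom(cfg)
  bone <- segmentBone(ph@intraop, autoBoneSeeds(ph@intraop))
  expect_gte(dice(bone, ph@truth$bone), 0.95)

  # a seed in soft tissue violates the HU window
  centre_idx <- matrix(round(imgDim(ph@intraop) / 2), 1)
  expect_error(segmentBone(ph@intraop, centre_idx), "window")

  # a constraint mask excluding one bone returns only the other
  w <- voxelCentres(ph@intraop)
  left <- Mask(array(w[, 1] < 0, imgDim(ph@intraop)), like = ph@intraop)
  seeds <- which(voxels(ph@intraop) >= 500 & array(w[, 1] < 0, imgDim(ph@intraop)),
                 arr.ind = TRUE)
  one <- segmentBone(ph@intraop, seeds[1, , drop = FALSE], constraint = left)
  expect_true(all(voxelCentres(ph@intraop)[which(voxels(one)), 1] < 0))
  expect_gt(sum(voxels(one)), 0.3 * sum(voxels(ph@truth$bone)))
})

test_that("air-gap segmentation: zero gap, known gap, fluid exclusion", {
  # flat-seated bevel-0 applicator: no air below the exit face
  cfg0 <- small_phantom_config(flat_top = TRUE, flat_top_z = 20,
                               cavity_depth_mm = 0, irregularity_mm = 0,
                               spec = applicatorSpec(3.5, 0),
                               tilt_deg = c(0, 0), target_gap_mm = 0)
  ph0 <- generatePhantom(cfg0)
  g0 <- segmentAirGap(ph0@intraop, ph0@truth$pose, cfg0@spec)
  expect_equal(sum(voxels(g0)), 0)
  expect_equal(maxAirGapDistance(g0, ph0@truth$pose, cfg0@spec), 0)

  cfg <- small_phantom_config(seed = 8L, noise_sigma_hu = 12)
  ph <- generatePhantom(cfg)
  gap <- segmentAirGap(ph@intraop, ph@truth$pose, cfg@spec)
  expect_gte(dice(gap, ph@truth$air_gap), 0.95)

  # fluid pooling at ~10 HU is tissue-like and never part of the gap
  cfgf <- small_phantom_config(seed = 8L, fluid_depth_mm = 4)
  phf <- generatePhantom(cfgf)
  gapf <- segmentAirGap(phf@intraop, phf@truth$pose, cfgf@spec)
  fluid <- voxels(phf@intraop) > -200 & voxels(phf@truth$cavity)
  expect_equal(sum(voxels(gapf) & fluid), 0)
})

test_that("air gap never overlaps the body mask", {
  for (sd in c(2L, 12L)) {
    cfg <- small_phantom_config(seed = sd, noise_sigma_hu = 10)
    ph <- generatePhantom(cfg)
    gap <- segmentAirGap(ph@intraop, ph@truth$pose, cfg@spec)
    body <- bodyMask(ph@intraop, wall = ph@truth$applicator_wall)
    expect_equal(sum(voxels(gap) & voxels(body)), 0)
  }
})

test_that("wall segmentation tolerates hint error and fails without a wall", {
  cfg <- small_phantom_config(seed = 3L)
  ph <- generatePhantom(cfg)
  hint <- list(point = c(0, 0, 25), direction = c(0, 0, -1))
  wall <- segmentApplicatorWall(ph@intraop, hint, cfg@spec)
  tw <- voxels(ph@truth$applicator_wall)
  expect_gte(sum(voxels(wall) & tw) / sum(tw), 0.9)

  # a hint 5 mm off gives the same wall (the tube neighbourhood is generous)
  hint2 <- list(point = c(5, 0, 25), direction = c(0, 0, -1))
  wall2 <- segmentApplicatorWall(ph@intraop, hint2, cfg@spec)
  expect_gt(dice(wall, wall2), 0.999)

  # no applicator present: segmentation must fail loudly
  expect_error(segmentApplicatorWall(ph@preop, hint, cfg@spec), "failed")
})

test_that("body mask: phantom recovery, hole filling, empty error", {
  cfg <- small_phantom_config(seed = 2L,
                              lowdens_hu = -800,
                              lowdens_centre = c(12, -10, -16),
                              lowdens_radius_mm = 6)
  ph <- generatePhantom(cfg)
  body <- bodyMask(ph@intraop, wall = ph@truth$applicator_wall)
  expect_gte(dice(body, ph@truth$body), 0.99)
  # the internal low-density region is retained by hole filling
  w <- voxelCentres(ph@intraop)
  inside_ld <- rowSums(sweep(w, 2, c(12, -10, -16), "-")^2) <= 4^2
  expect_true(all(voxels(body)[inside_ld]))

  air <- CTVolume(array(-1000, c(8, 8, 8)))
  expect_error(bodyMask(air), "empty")
})

test_that("maximum air-gap distance: flat standoff and irregular-bed oracle", {
  # flat interface, bevel 0, 10 mm standoff
  cfg <- small_phantom_config(flat_top = TRUE, flat_top_z = 20,
                              cavity_depth_mm = 0, irregularity_mm = 0,
                              spec = applicatorSpec(3.5, 0),
                              tilt_deg = c(0, 0), target_gap_mm = 10)
  ph <- generatePhantom(cfg)
  g <- segmentAirGap(ph@intraop, ph@truth$pose, cfg@spec)
  expect_lt(abs(maxAirGapDistance(g, ph@truth$pose, cfg@spec) - 10), 1.5)

  # irregular bed: within one voxel of the surface-function oracle
  cfgi <- small_phantom_config(seed = 14L, irregularity_mm = 5,
                               target_gap_mm = 12)
  phi <- generatePhantom(cfgi)
  gi <- segmentAirGap(phi@intraop, phi@truth$pose, cfgi@spec)
  expect_lt(abs(maxAirGapDistance(gi, phi@truth$pose, cfgi@spec) -
                phi@truth$gap_mm), 1.5)
})
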