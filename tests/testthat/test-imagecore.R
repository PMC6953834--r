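test_that("NIfTI write/read round-trips values and grid metadata", {
  set.seed(1)
  v <- CTVolume(array(rnorm(20^3, sd = 300), c(20, 20, 20)),
                spacing = c(1.3, 1.3, 5.0), origin = c(-10, 5, 7))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  b <- readVolume(f)
  expect_identical(voxels(b), voxels(v))
  expect_equal(spacing(b), c(1.3, 1.3, 5.0), tolerance = 1e-6)
  expect_equal(origin(b), origin(v), tolerance = 1e-5)

  # masks round-trip as 8-bit
  m <- Mask(voxels(v) > 0, like = v)
  fm <- tempfile(fileext = ".nii.gz")
  writeVolume(m, fm)
  m2 <- readMask(fm, like = b)
  expect_identical(voxels(m2), voxels(m))
})

test_that("readVolume rejects non-3D images and unreadable files", {
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(rnorm(100), 10, 10))
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), "3D")
  expect_error(readVolume(tempfile(fileext = ".nii")), "no such file")
  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  suppressWarnings(expect_error(readVolume(bad)))
})

test_that("writeVolume fails cleanly on a missing parent directory", {
  v <- CTVolume(array(0, c(4, 4, 4)))
  expect_error(writeVolume(v, file.path(tempdir(), "no_such_dir", "x.nii.gz")),
               "parent directory")
})

test_that("MetaImage volumes are readable", {
  # construct a minimal uncompressed .mha by hand
  d <- c(7L, 6L, 5L)
  vals <- array(as.integer(round(rnorm(prod(d), 0, 200))), d)
  path <- tempfile(fileext = ".mha")
  con <- file(path, "wb")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               paste("DimSize =", paste(d, collapse = " ")),
               "ElementSpacing = 1.1 1.2 2.5", "Offset = -3 4 5",
               "ElementType = MET_SHORT", "ElementDataFile = LOCAL"), con)
  writeBin(as.integer(vals), con, size = 2, endian = "little")
  close(con)
  v <- readVolume(path)
  expect_equal(voxels(v), array(as.double(vals), d))
  expect_equal(spacing(v), c(1.1, 1.2, 2.5))
  expect_equal(origin(v), c(-3, 4, 5))
})

test_that("isotropic resampling preserves constants and affine ramps", {
  cv <- CTVolume(array(137, c(12, 12, 12)), spacing = c(1.1, 1.3, 2.0))
  r <- resampleIsotropic(cv, 1.5)
  expect_true(all(abs(voxels(r) - 137) < 1e-9))
  expect_equal(spacing(r), rep(1.5, 3))
  expect_equal(imgDim(r), ceiling(c(12, 12, 12) * c(1.1, 1.3, 2.0) / 1.5))

  # linear HU ramp along x is exact for trilinear at interior voxels
  d <- c(20, 10, 10)
  ramp <- CTVolume(array(rep(seq_len(d[1]) * 10, prod(d[2:3])), d),
                   spacing = c(1.1, 1.5, 1.5))
  rr <- resampleIsotropic(ramp, 1.5)
  w <- voxelCentres(rr)
  inside <- w[, 1] <= (d[1] - 1) * 1.1 - 0.01
  expected <- 10 + w[inside, 1] / 1.1 * 10
  expect_equal(voxels(rr)[inside], expected, tolerance = 1e-9)
})

test_that("resampling matches a direct trilinear oracle at output centres", {
  set.seed(7)
  d <- c(40, 40, 40)
  v <- CTVolume(array(rnorm(prod(d), 0, 100), d), spacing = rep(1.1, 3))
  r <- resampleIsotropic(v, 1.5)
  idx0 <- sweep(voxelCentres(r), 2, v@origin, "-") / 1.1
  interior <- rowSums(idx0 >= 0 & idx0 <= rep(d - 1, each = nrow(idx0))) == 3
  pick <- which(interior)[seq(1, sum(interior), length.out = 500)]
  expect_equal(voxels(r)[pick], trilinear_oracle(voxels(v), idx0[pick, ]),
               tolerance = 1e-10)
})

test_that("resampling twice at the same spacing is stable on constants", {
  cv <- CTVolume(array(42, c(10, 14, 9)), spacing = c(1.2, 0.9, 3.1))
  r1 <- resampleIsotropic(cv, 1.5)
  r2 <- resampleIsotropic(r1, 1.5)
  expect_lt(max(abs(voxels(r2) - 42)), 1e-6)
})

test_that("HU to density calibration anchors, interpolation and monotonicity", {
  expect_equal(huToDensity(0), 1.000)
  expect_equal(huToDensity(-1000), 0.00121)
  # independent linear interpolation between the shipped knots
  tab <- loadHuDensityTable()
  hu <- c(-730, -250, 133, 640)
  expected <- vapply(hu, function(h) {
    i <- max(which(tab[, 1] <= h))
    tab[i, 2] + (h - tab[i, 1]) / (tab[i + 1, 1] - tab[i, 1]) *
      (tab[i + 1, 2] - tab[i, 2])
  }, numeric(1))
  expect_equal(huToDensity(hu), expected, tolerance = 1e-12)
  # clamped ends, monotone everywhere (property over random sequences)
  expect_equal(huToDensity(c(-5000, 4000)), c(0.00121, 1.59))
  set.seed(11)
  for (rep in 1:5) {
    x <- sort(runif(100, -1500, 2500))
    expect_true(all(diff(huToDensity(x)) >= 0))
  }
  # CTVolume input returns a DensityVolume on the same grid
  v <- CTVolume(array(c(-1000, 0, 500, 1000), c(2, 2, 1)))
  dv <- huToDensity(v)
  expect_s4_class(dv, "DensityVolume")
  expect_true(all(voxels(dv) >= 0))
})

test_that("RMS HU difference matches the direct formula", {
  set.seed(3)
  a <- CTVolume(array(rnorm(1000, 0, 100), c(10, 10, 10)))
  m <- Mask(array(runif(1000) > 0.4, c(10, 10, 10)), like = a)
  expect_equal(rmsHuDifference(a, a, m), 0)
  b <- CTVolume(voxels(a) + 10)
  expect_equal(rmsHuDifference(a, b, m), 10)
  b2 <- CTVolume(array(rnorm(1000, 0, 100), c(10, 10, 10)))
  sel <- voxels(m)
  expect_equal(rmsHuDifference(a, b2, m),
               sqrt(mean((voxels(a)[sel] - voxels(b2)[sel])^2)))
  empty <- Mask(array(FALSE, c(10, 10, 10)), like = a)
  expect_error(rmsHuDifference(a, b, empty), "empty mask")
})
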