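test_that("ct_volume validates its invariants", {
  expect_error(ct_volume(array(1, c(2, 2)), ), "3D")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(ct_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  v <- ct_volume(array(0, c(2, 3, 4)), spacing = c(2, 0.7, 0.7))
  expect_identical(dim(v$intensities), c(2L, 3L, 4L))
})

test_that("seed sets reject overlapping object/background voxels", {
  a <- array(FALSE, c(2, 2, 2)); b <- a
  a[1, 1, 1] <- TRUE
  expect_s3_class(seed_set(a, b), "seed_set")
  b[1, 1, 1] <- TRUE
  expect_error(seed_set(a, b), "overlap")
})

test_that("NIfTI volumes round-trip bit-exactly with spacing", {
  v <- tiny_volume(seed = 1)
  v$spacing <- c(2.5, 0.7, 0.7)
  path <- file.path(tempdir(), "vol.nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(back$intensities, v$intensities)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
})

test_that("MetaImage volumes round-trip bit-exactly", {
  v <- tiny_volume(seed = 2)
  v$spacing <- c(3, 0.486, 0.486)
  path <- file.path(tempdir(), "vol.mhd")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(back$intensities, v$intensities)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
})

test_that("DICOM series round-trip integer HU and header spacing", {
  arr <- array(sample(-1000:1500, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  v <- ct_volume(arr, spacing = c(1.0, 0.486, 0.486))
  dir <- file.path(tempdir(), "dcm_series")
  write_volume(v, dir, format = "dicom-series")
  back <- read_volume(dir)
  expect_equal(back$intensities, v$intensities)
  expect_equal(back$spacing, c(1.0, 0.486, 0.486), tolerance = 1e-6)
})

test_that("DICOM reading flags missing and inconsistent series", {
  empty <- file.path(tempdir(), "empty_dir")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_volume(empty, format = "dicom-series"), "no DICOM")
  # irregular slice positions: warn and fall back to the median distance
  v <- ct_volume(array(0, c(3, 4, 4)))
  dir <- file.path(tempdir(), "dcm_irregular")
  write_volume(v, dir, format = "dicom-series")
  # move the last slice: positions 0, 1, 2.5
  sl <- read_volume(dir)  # consumes the regular series fine
  v2 <- ct_volume(array(0, c(1, 4, 4)), origin = c(2.5, 0, 0))
  tmp <- file.path(tempdir(), "dcm_one")
  write_volume(v2, tmp, format = "dicom-series")
  file.copy(file.path(tmp, "slice_0001.dcm"),
            file.path(dir, "slice_0003.dcm"), overwrite = TRUE)
  expect_warning(back <- read_volume(dir), "inconsistent slice spacing")
  expect_equal(back$spacing[1], 1.25)
})

test_that("masks round-trip losslessly and preserve spacing to 1e-6 mm", {
  m <- segmentation_mask(random_blob(c(5, 6, 7)),
                         spacing = c(1.23456789, 0.5, 0.5))
  for (ext in c("m.nii.gz", "m.mhd")) {
    path <- file.path(tempdir(), ext)
    write_mask(m, path)
    back <- read_mask(path)
    expect_identical(back$labels, m$labels)
    expect_equal(back$spacing, m$spacing, tolerance = 1e-6)
  }
  expect_error(write_mask(m, file.path(tempdir(), "m.xyz")), "extension")
})

test_that("seed contours rasterize as cylindrical extrusions", {
  v <- ct_volume(array(0, c(6, 12, 12)))
  sq <- rbind(c(3, 3), c(3, 8), c(8, 8), c(8, 3))
  bgp <- rbind(c(10, 10), c(10, 11.5), c(11.5, 11.5), c(11.5, 10))
  seeds <- rasterize_seeds(list(
    list(label = "object", slices = c(3, 5), vertices = sq),
    list(label = "background", slices = c(1, 6), vertices = bgp)), v)
  # filled square exactly on slices 3..5, nothing elsewhere
  expect_true(all(seeds$object_mask[3:5, 3:8, 3:8]))
  expect_equal(sum(seeds$object_mask), 3 * 36)
  expect_false(any(seeds$object_mask[c(1, 2, 6), , ]))
  # intersecting object/background polygons violate the disjointness invariant
  expect_error(rasterize_seeds(list(
    list(label = "object", slices = c(1, 2), vertices = sq),
    list(label = "background", slices = c(2, 3),
         vertices = sq + 2)), v), "overlap")
  # polygon outside the grid
  expect_error(rasterize_seeds(list(
    list(label = "object", slices = c(1, 2), vertices = sq + 10)), v),
    "outside")
  # missing seed class
  expect_error(rasterize_seeds(list(
    list(label = "object", slices = c(1, 2), vertices = sq)), v),
    "background")
})

test_that("label volumes convert to seed sets", {
  lab <- array(0, c(3, 4, 4))
  lab[1, 1, 1] <- 1; lab[2, 2, 2] <- 2
  s <- seeds_from_labels(lab)
  expect_true(s$object_mask[1, 1, 1])
  expect_true(s$background_mask[2, 2, 2])
  expect_equal(sum(s$object_mask) + sum(s$background_mask), 2)
  lab[3, 3, 3] <- 7
  expect_error(seeds_from_labels(lab), "0, 1, 2")
})
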