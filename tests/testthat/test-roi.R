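test_that("bounding-box cropping records offsets and re-embeds exactly", {
  v <- tiny_volume(c(20, 30, 30), seed = 3)
  bbox <- rbind(c(4, 18), c(5, 25), c(10, 30))
  sub <- crop_bbox(v, bbox)
  expect_identical(dim(sub$intensities), c(15L, 21L, 21L))
  expect_identical(attr(sub, "offset"), c(4L, 5L, 10L))
  # identity crop
  full <- crop_bbox(v, rbind(c(1, 20), c(1, 30), c(1, 30)))
  expect_identical(full$intensities, v$intensities)
  # a mask built on the crop lands back on its original voxels
  m <- array(FALSE, dim(sub$intensities)); m[2, 3, 4] <- TRUE
  emb <- embed_mask(segmentation_mask(m, v$spacing), attr(sub, "offset"),
                    dim(v$intensities))
  expect_identical(which(emb$labels),
                   which(array(seq_len(prod(dim(v$intensities))),
                               dim(v$intensities)) ==
                         ((10 + 4 - 1 - 1) * 20 * 30 +
                          (5 + 3 - 1 - 1) * 20 + (4 + 2 - 1))))
  expect_error(crop_bbox(v, rbind(c(5, 4), c(1, 2), c(1, 2))), "empty")
  expect_error(crop_bbox(v, rbind(c(1, 25), c(1, 2), c(1, 2))), "outside")
})

test_that("a 512x512x20 volume crops to the published ROI shape", {
  v <- ct_volume(array(0L, c(20, 512, 512)))
  sub <- crop_bbox(v, rbind(c(1, 20), c(100, 392), c(120, 395)))
  expect_identical(dim(sub$intensities), c(20L, 293L, 276L))
})

test_that("crossline detection finds the spine centroid on phantoms", {
  ph <- generate_phantom(phantom_spec(dim = c(16, 48, 48), bone = TRUE,
                                      noise = 0, blur = 0))
  cl <- detect_crossline(ph$volume, bone_threshold = 400)
  expect_true(abs(cl$center[1] - round(0.85 * 48)) <= 1)
  expect_true(abs(cl$center[2] - 24) <= 1)
  # no bone anywhere: actionable error
  soft <- generate_phantom(phantom_spec(dim = c(16, 48, 48), bone = FALSE,
                                        noise = 0, blur = 0))
  expect_error(detect_crossline(soft$volume), "manual")
  # threshold below soft tissue: contract only promises a centre in-grid
  cl2 <- detect_crossline(ph$volume, bone_threshold = 30)
  expect_true(cl2$center[1] >= 1 && cl2$center[1] <= 48)
  expect_true(cl2$center[2] >= 1 && cl2$center[2] <= 48)
})

test_that("quadrant elimination removes exactly the selected quadrant", {
  v <- ct_volume(array(0, c(3, 10, 10)))
  ex <- eliminate_quadrant(v, c(6, 6))
  expect_equal(sum(ex), 3 * 5 * 5)           # quarter of an even grid
  expect_equal(sum(ex), prod(3, 10 - 6 + 1, 10 - 6 + 1))
  expect_true(all(ex[, 6:10, 6:10]))
  ex_all <- eliminate_quadrant(v, c(1, 1))
  expect_true(all(ex_all))
  ex_lt <- eliminate_quadrant(v, c(4, 7), quadrant = "left-top")
  expect_equal(sum(ex_lt), 3 * 4 * 7)
  expect_error(eliminate_quadrant(v, c(11, 2)), "outside")
})

test_that("ROI reduction refuses to drop object seeds", {
  obj <- array(FALSE, c(3, 8, 8)); obj[2, 7, 7] <- TRUE
  bg <- array(FALSE, c(3, 8, 8)); bg[1, 1, 1] <- TRUE
  seeds <- seed_set(obj, bg)
  expect_error(check_roi_keeps_seeds(seeds,
                 bbox = rbind(c(1, 3), c(1, 4), c(1, 4))), "seed")
  ex <- eliminate_quadrant(ct_volume(array(0, c(3, 8, 8))), c(5, 5))
  expect_error(check_roi_keeps_seeds(seeds, exclusion = ex), "seed")
  expect_true(check_roi_keeps_seeds(seeds,
                bbox = rbind(c(1, 3), c(1, 8), c(1, 8))))
})

test_that("auto bounding boxes cover seeds with the requested margin", {
  obj <- array(FALSE, c(10, 30, 30)); obj[5, 14:16, 14:16] <- TRUE
  bg <- array(FALSE, c(10, 30, 30)); bg[5, 20, 20] <- TRUE
  v <- ct_volume(array(0, c(10, 30, 30)), spacing = c(2, 1, 1))
  b <- auto_bbox(seed_set(obj, bg), v, margin_mm = 4)
  expect_identical(b[, 1], c(3L, 10L, 10L))   # 4 mm = 2 slices / 4 px
  expect_identical(b[, 2], c(7L, 24L, 24L))
})
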