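test_that("LBP codes follow the thresholded neighbour comparisons", {
  const <- matrix(50, 9, 9)
  expect_true(all(lbp_map(const) == 0))        # nobody exceeds center + zeta
  # center lower than all neighbours by more than zeta: all m bits set
  pit <- matrix(100, 9, 9); pit[5, 5] <- 0
  expect_equal(lbp_map(pit)[5, 5], 63)         # 2^6 - 1
  expect_true(all(lbp_map(pit) >= 0 & lbp_map(pit) <= 63))
  # m = 4 samples the axis neighbours exactly: a single hot neighbour at
  # angle index t = 2 (angle pi, one column left) sets only bit 2
  one <- matrix(0, 9, 9); one[5, 4] <- 10
  expect_equal(lbp_map(one, m = 4, zeta = 1.6)[5, 5], 4)
  expect_error(lbp_map(const, m = 3), "at least 4")
  expect_error(lbp_map(matrix(0, 2, 2)), "smaller")
})

test_that("integral-histogram profiles equal the naive window histogram", {
  set.seed(5)
  for (trial in 1:3) {
    f <- matrix(runif(16 * 16, 0, 100), 16, 16)
    breaks <- seq(0, 100, length.out = 9)
    pr <- local_profiles(f, window = 5, breaks = breaks)
    expect_equal(pr$prob, naive_profiles(f, 5, breaks), tolerance = 1e-12)
  }
  # constant input degenerates to a single occupied bin
  pr <- local_profiles(matrix(7, 8, 8), window = 3, breaks = c(0, 5, 10, 15))
  expect_true(all(pr$prob[, , 2] == 1))
  expect_true(all(apply(pr$prob, c(1, 2), sum) == 1))
  # a window covering the whole slice gives the same profile everywhere
  f <- matrix(runif(49), 7, 7)
  pr2 <- local_profiles(f, window = 13, breaks = seq(0, 1, 0.25))
  expect_equal(pr2$prob[1, 1, ], pr2$prob[4, 7, ])
  expect_equal(pr2$prob[2, 3, ], pr2$prob[7, 1, ])
})

test_that("W1 distance is a metric with the point-mass closed form", {
  vals <- seq(10, 80, by = 10)
  point <- function(i) { p <- numeric(8); p[i] <- 1; p }
  expect_equal(w1_distance(point(3), point(3), vals), 0)
  expect_equal(w1_distance(point(2), point(6), vals), 40)  # |a - b|
  set.seed(8)
  for (trial in 1:10) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    r <- runif(8); r <- r / sum(r)
    expect_gte(w1_distance(p, q, vals), 0)
    expect_equal(w1_distance(p, q, vals), w1_distance(q, p, vals))
    expect_lte(w1_distance(p, r, vals),
               w1_distance(p, q, vals) + w1_distance(q, r, vals) + 1e-12)
  }
  expect_error(w1_distance(point(2), point(2)[1:5], vals), "matching")
})

test_that("the global appearance model is the seed mean with W1 spread", {
  vals <- c(0, 1, 2, 3, 4, 5)
  pa <- c(0, 1, 0, 0, 0, 0)   # point mass at 1
  pb <- c(0, 0, 0, 0, 1, 0)   # point mass at 4
  m <- global_model(rbind(pa, pb), values = vals, sigma_floor = 1e-3)
  expect_equal(as.numeric(m$mean), c(0, 0.5, 0, 0, 0.5, 0))
  # each point profile is W1 = 1.5 from the mean; sigma2 = mean squared
  expect_equal(m$sigma2, 1.5^2)
  # identical seed profiles: mean = profile, variance at the floor
  m2 <- global_model(rbind(pa, pa, pa), values = vals, sigma_floor = 1e-3)
  expect_equal(as.numeric(m2$mean), pa)
  expect_equal(m2$sigma2, 1e-3)
})

test_that("certainty fields scale as W1 / sigma^2", {
  set.seed(9)
  f <- matrix(runif(100, 0, 50), 10, 10)
  breaks <- seq(0, 50, length.out = 9)
  pr <- local_profiles(f, 5, breaks)
  seed2d <- matrix(FALSE, 10, 10); seed2d[4:6, 4:6] <- TRUE
  m <- global_model(pr, seed2d)
  cc <- certainty_field(pr, m)
  expect_true(all(cc >= 0))
  m4 <- m; m4$sigma2 <- 4 * m$sigma2
  expect_equal(certainty_field(pr, m4), cc / 4)   # doubling sigma quarters C
  # a pixel whose window is the seed appearance scores ~ 0
  g <- matrix(20, 10, 10)
  prg <- local_profiles(g, 5, breaks)
  mg <- global_model(prg, seed2d)
  expect_true(all(certainty_field(prg, mg) == 0))
})

test_that("certainty is invariant to HU shifts with shifted bin edges", {
  set.seed(10)
  f <- matrix(runif(144, 10, 60), 12, 12)
  breaks <- seq(0, 70, length.out = 15)
  seed2d <- matrix(FALSE, 12, 12); seed2d[5:8, 5:8] <- TRUE
  c1 <- certainty_field(pr1 <- local_profiles(f, 5, breaks),
                        global_model(pr1, seed2d))
  c2 <- certainty_field(pr2 <- local_profiles(f + 500, 5, breaks + 500),
                        global_model(pr2, seed2d))
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("the enhanced image is flat on uniform volumes, in [0,1] always", {
  u <- ct_volume(array(100, c(3, 16, 16)))
  obj <- array(FALSE, c(3, 16, 16)); obj[2, 6:10, 6:10] <- TRUE
  bg <- array(FALSE, c(3, 16, 16)); bg[1, 1, 1] <- TRUE
  enh <- enhanced_image(u, seed_set(obj, bg),
                        interval = intensity_interval(80, 120))
  expect_true(all(enh$enhanced == 0))
  ph <- generate_phantom(phantom_spec(dim = c(16, 32, 32)))
  enh2 <- enhanced_image(ph$volume, ph$seeds)
  expect_true(all(enh2$enhanced >= 0 & enh2$enhanced <= 1))
})

test_that("enhanced maxima concentrate near the phantom organ boundary", {
  ph <- generate_phantom(phantom_spec(dim = c(16, 48, 48)))
  enh <- enhanced_image(ph$volume, ph$seeds)
  k <- 8
  cb <- contour_band(ph$truth$labels[k, , ])
  sl <- enh$enhanced[k, , ]
  # certainty along the boundary strip clearly dominates the liver interior
  expect_gt(mean(sl[cb$band]), 2 * mean(sl[cb$interior]))
})
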