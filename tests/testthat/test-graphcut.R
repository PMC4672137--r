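test_that("the Gaussian affinity matches its closed form", {
  expect_equal(gaussian_affinity(120, 120, 10), 1)
  expect_equal(gaussian_affinity(120, 130, 10), exp(-0.5))
  diffs <- seq(0, 50, 5)
  k <- gaussian_affinity(100, 100 + diffs, 10)
  expect_true(all(diff(k) < 0))                       # strictly decreasing
  expect_error(gaussian_affinity(1, 2, 0), "positive")
  expect_equal(modulated_affinity(1, 0.999), 0.999)
  expect_equal(modulated_affinity(0.7, 1), 0.7)       # plain-GC baseline
})

test_that("a two-voxel graph resolves by enumerating the four labelings", {
  v <- ct_volume(array(c(100, 101), c(1, 1, 2)))
  lik <- list(pr_object = array(c(0.9, 0.8), c(1, 1, 2)),
              pr_background = array(c(0.2, 0.3), c(1, 1, 2)))
  g <- build_graph(v, lik, params = energy_params(lambda = 5, sigma = 10))
  sol <- solve_min_cut(g)
  # enumerate all four labelings with the same energy function
  energies <- sapply(list(c(F, F), c(F, T), c(T, F), c(T, T)), function(l)
    cut_energy(array(l, c(1, 1, 2)), g))
  expect_equal(cut_energy(sol$mask, g), min(energies))
  # the strong n-link forces a uniform labeling on the cheaper side
  expect_true(all(sol$mask$labels) || all(!sol$mask$labels))
  expect_true(all(sol$mask$labels))  # object likelihoods dominate here
})

test_that("fully seeded volumes return exactly the seeded labeling", {
  v <- tiny_volume(c(2, 3, 3), seed = 12)
  obj <- array(FALSE, c(2, 3, 3)); obj[1, , ] <- TRUE
  seeds <- seed_set(obj, !obj)
  lik <- list(pr_object = array(0.5, c(2, 3, 3)),
              pr_background = array(0.5, c(2, 3, 3)))
  sol <- solve_min_cut(build_graph(v, lik, seeds = seeds))
  expect_identical(sol$mask$labels, obj)
})

test_that("a decoupled graph (lambda -> 0) reduces to per-voxel argmin", {
  set.seed(13)
  v <- tiny_volume(c(3, 4, 4), seed = 13)
  po <- array(runif(48, 0.01, 0.99), c(3, 4, 4))
  pb <- array(runif(48, 0.01, 0.99), c(3, 4, 4))
  g <- build_graph(v, list(pr_object = po, pr_background = pb),
                   params = energy_params(lambda = 1e-12, sigma = 10))
  sol <- solve_min_cut(g)
  expect_identical(sol$mask$labels, po > pb)
})

test_that("max-flow equals the cut energy of the returned labeling", {
  set.seed(14)
  for (trial in 1:20) {
    gg <- random_grid_graph()
    v <- ct_volume(array(100, gg$dim))
    lik <- list(pr_object = array(exp(-gg$tcap), gg$dim),
                pr_background = array(exp(-gg$scap), gg$dim))
    g <- build_graph(v, lik, params = energy_params(lambda = 1, sigma = 10))
    g$ncap <- gg$ncap          # random boundary weights on the same lattice
    sol <- solve_min_cut(g)
    expect_equal(sol$flow, cut_energy(sol$mask, g), tolerance = 1e-9)
  }
})

test_that("the solver agrees with an independent max-flow implementation", {
  set.seed(15)
  for (trial in 1:25) {
    gg <- random_grid_graph()
    n <- prod(gg$dim)
    res <- swarmcut:::.maxflow_bk(gg$edges - 1L, gg$ncap, gg$scap, gg$tcap)
    g <- igraph::graph_from_edgelist(
      rbind(gg$edges + 2L, cbind(1L, seq_len(n) + 2L),
            cbind(seq_len(n) + 2L, 2L)), directed = FALSE)
    mf <- igraph::max_flow(g, 1, 2,
                           capacity = c(gg$ncap, gg$scap, gg$tcap))
    expect_equal(res$flow, mf$value, tolerance = 1e-9)
  }
})

test_that("solver energy never exceeds the ground-truth labeling energy", {
  ph <- generate_phantom(phantom_spec(dim = c(16, 32, 32)))
  lik <- likelihood_field(ph$volume, ph$seeds)
  g <- build_graph(ph$volume, lik, seeds = ph$seeds)
  sol <- solve_min_cut(g)
  expect_lte(cut_energy(sol$mask, g), cut_energy(ph$truth, g) + 1e-9)
  expect_true(all(g$ncap >= 0) && all(is.finite(g$ncap)))
  expect_true(all(g$scap >= 0) && all(is.finite(g$scap)))
  # seeded voxels keep their seeded label
  expect_true(all(sol$mask$labels[ph$seeds$object_mask]))
  expect_false(any(sol$mask$labels[ph$seeds$background_mask]))
})

test_that("increasing lambda never increases the cut boundary length", {
  ph <- generate_phantom(phantom_spec(dim = c(16, 32, 32), noise = 5))
  lik <- likelihood_field(ph$volume, ph$seeds)
  boundary_len <- sapply(c(0.05, 0.15, 0.5, 2), function(lam) {
    g <- build_graph(ph$volume, lik, seeds = ph$seeds,
                     params = energy_params(lambda = lam, sigma = 10))
    lab <- as.vector(solve_min_cut(g)$mask$labels)
    sum(lab[g$edges[, 1] + 1L] != lab[g$edges[, 2] + 1L])
  })
  expect_true(all(diff(boundary_len) <= 0))
})

test_that("swarm modulation enters the n-links through the edge pheromone", {
  v <- ct_volume(array(100, c(2, 2, 2)))
  lik <- list(pr_object = array(0.5, c(2, 2, 2)),
              pr_background = array(0.5, c(2, 2, 2)))
  tau <- array(0.001, c(2, 2, 2))
  tau[1, 1, 1] <- 0.999; tau[1, 1, 2] <- 0.5
  g0 <- build_graph(v, lik, params = energy_params(lambda = 1, sigma = 10))
  g1 <- build_graph(v, lik, tau = tau,
                    params = energy_params(lambda = 1, sigma = 10))
  # identical intensities: K = 1, so the n-link weight is lambda * B
  expect_true(all(abs(g0$ncap - 1) < 1e-12))
  # the in-slice edge (1,1,1)-(1,1,2) takes max(tau) = 0.999 -> B = 0.001
  in_slice <- which(g1$edges[, 1] == 0 & g1$edges[, 2] == 4)
  expect_equal(g1$ncap[in_slice], 0.001)
})
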