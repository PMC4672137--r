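# Graph construction and min-cut: 6-connected 3D lattice with Gaussian
# n-links modulated by the swarm factor, -log likelihood t-links, hard seed
# constraints, and a Boykov-Kolmogorov max-flow solve.

#' Energy parameters
#'
#' @param lambda smoothness weight (default 0.15).
#' @param sigma Gaussian scale of the boundary term in HU (default 10).
#' @param hard_seed_weight terminal capacity for seed constraints; by default
#'   derived from the graph (10 x the largest possible cut contribution) so
#'   seed links are never cut.
#' @return A named list of class `energy_params`.
#' @export
energy_params <- function(lambda = 0.15, sigma = 10,
                          hard_seed_weight = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(lambda = lambda, sigma = sigma,
                 hard_seed_weight = hard_seed_weight),
            class = "energy_params")
}

#' Gaussian intensity affinity
#'
#' `K(u, v) = exp(-(I_u - I_v)^2 / (2 sigma^2))`: close to 1 for similar
#' intensities (expensive to cut), small across strong edges.
#'
#' @param iu,iv intensities in HU (vectorized).
#' @param sigma Gaussian scale in HU.
#' @return Affinities in (0, 1\].
#' @export
gaussian_affinity <- function(iu, iv, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  exp(-(iu - iv)^2 / (2 * sigma^2))
}

#' Swarm-modulated affinity
#'
#' @param k Gaussian affinity value(s).
#' @param b swarm boundary factor(s) `1 - tau`; `b = 1` recovers the plain
#'   (unmodulated) graph-cut boundary term.
#' @return `b * k`.
#' @export
modulated_affinity <- function(k, b) b * k

#' Build the segmentation graph
#'
#' n-link weight `lambda * B(u,v) * K(u,v)` for every 6-neighbour pair;
#' terminal links carry the data costs (`source = -log Pr(x|B)`,
#' `sink = -log Pr(x|O)`, so cutting the sink link labels the voxel object).
#' Object seeds get a hard source link; background seeds and quadrant-excluded
#' voxels a hard sink link.
#'
#' @param volume a [ct_volume].
#' @param likelihoods list with `pr_object`, `pr_background` (see
#'   [likelihood_field]).
#' @param tau 3D pheromone array, or `NULL` to disable swarm modulation
#'   (`B = 1`).
#' @param seeds a [seed_set].
#' @param exclusion logical array of quadrant-excluded voxels, or `NULL`.
#' @param params an [energy_params] list.
#' @param eps_floor likelihood floor for the data costs.
#' @return A `seg_graph` list: `edges` (0-based node pairs), `ncap`, `scap`,
#'   `tcap`, `dim`, `spacing`, `hard` (logical array of hard-constrained
#'   voxels), `hard_weight`.
#' @export
build_graph <- function(volume, likelihoods, tau = NULL, seeds = NULL,
                        exclusion = NULL, params = energy_params(),
                        eps_floor = 1e-6) {
  d <- vol_dim(volume)
  n <- prod(d)
  stopifnot(identical(dim(likelihoods$pr_object), d),
            identical(dim(likelihoods$pr_background), d))
  I <- volume$intensities
  idx <- array(seq_len(n), d)

  edge_block <- function(axis) {
    sel_lo <- switch(axis,
      list(1:(d[1] - 1), seq_len(d[2]), seq_len(d[3])),
      list(seq_len(d[1]), 1:(d[2] - 1), seq_len(d[3])),
      list(seq_len(d[1]), seq_len(d[2]), 1:(d[3] - 1)))
    sel_hi <- switch(axis,
      list(2:d[1], seq_len(d[2]), seq_len(d[3])),
      list(seq_len(d[1]), 2:d[2], seq_len(d[3])),
      list(seq_len(d[1]), seq_len(d[2]), 2:d[3]))
    a <- as.vector(idx[sel_lo[[1]], sel_lo[[2]], sel_lo[[3]]])
    b <- as.vector(idx[sel_hi[[1]], sel_hi[[2]], sel_hi[[3]]])
    K <- gaussian_affinity(I[a], I[b], params$sigma)
    B <- if (is.null(tau)) 1 else {
      ta <- tau[a]; tb <- tau[b]
      # slice axis = inter-slice edges (mean); in-slice edges take the max
      tuv <- if (axis == 1) (ta + tb) / 2 else pmax(ta, tb)
      boundary_factor(tuv)
    }
    list(a = a, b = b, w = params$lambda * modulated_affinity(K, B))
  }
  if (d[1] > 1 || d[2] > 1 || d[3] > 1) {
    blocks <- lapply(which(d > 1), edge_block)
    ea <- unlist(lapply(blocks, `[[`, "a"))
    eb <- unlist(lapply(blocks, `[[`, "b"))
    ew <- unlist(lapply(blocks, `[[`, "w"))
  } else {
    ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  }

  scap <- as.numeric(data_cost(likelihoods$pr_background, eps_floor))
  tcap <- as.numeric(data_cost(likelihoods$pr_object, eps_floor))

  hard <- array(FALSE, d)
  hw <- params$hard_seed_weight
  if (is.null(hw)) {
    max_t <- if (n > 0) max(scap, tcap) else 0
    max_n <- if (length(ew)) max(ew) else 0
    hw <- 10 * (max_t + 6 * max_n) + 1
  }
  if (!is.null(seeds)) {
    if (!is.null(exclusion) && any(seeds$object_mask & exclusion))
      stop("object seeds fall inside the excluded quadrant")
    obj <- as.vector(seeds$object_mask)
    bg <- as.vector(seeds$background_mask)
    scap[obj] <- hw; tcap[obj] <- 0
    scap[bg] <- 0; tcap[bg] <- hw
    hard <- hard | seeds$object_mask | seeds$background_mask
  }
  if (!is.null(exclusion)) {
    ex <- as.vector(exclusion)
    scap[ex] <- 0; tcap[ex] <- hw
    hard <- hard | exclusion
  }

  structure(list(edges = cbind(ea, eb) - 1L, ncap = ew, scap = scap,
                 tcap = tcap, dim = d, spacing = volume$spacing,
                 hard = hard, hard_weight = hw),
            class = "seg_graph")
}

#' Solve the min-cut
#'
#' Globally optimal binary labeling of the submodular pairwise energy via
#' Boykov-Kolmogorov max-flow; the flow value equals the cut capacity.
#'
#' @param graph a `seg_graph` from [build_graph].
#' @return List with `mask` (a [segmentation_mask], `TRUE` = object/source
#'   side) and `flow` (max-flow value).
#' @export
solve_min_cut <- function(graph) {
  res <- .maxflow_bk(graph$edges, graph$ncap, graph$scap, graph$tcap)
  labels <- array(res$label, graph$dim)
  list(mask = segmentation_mask(labels, spacing = graph$spacing),
       flow = res$flow)
}

#' Energy of a labeling
#'
#' `sum_u D_u(label_u) + lambda * sum_(u,v) B K [label_u != label_v]`,
#' excluding the data terms of hard-constrained voxels (their capacities are
#' artificial).
#'
#' @param labels a [segmentation_mask] or logical array.
#' @param graph the `seg_graph` the labeling refers to.
#' @return Scalar energy.
#' @export
cut_energy <- function(labels, graph) {
  lab <- as.vector(as_mask_array(labels))
  if (length(lab) != prod(graph$dim)) stop("labeling does not match graph")
  soft <- !as.vector(graph$hard)
  data_e <- sum(ifelse(lab[soft], graph$tcap[soft], graph$scap[soft]))
  a <- graph$edges[, 1] + 1L; b <- graph$edges[, 2] + 1L
  smooth_e <- sum(graph$ncap[lab[a] != lab[b]])
  data_e + smooth_e
}
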