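# Variant ant-colony optimization: per-slice pheromone fields of boundary
# confidence from ant walks on the enhanced image, and the swarm factor
# B = 1 - tau that modulates the Gaussian boundary term.

#' Parameters of the variant ant-colony engine
#'
#' Pheromone trails start at `tau0` and stay inside `[tau_min, tau_max]`
#' after every update. Ants move on the 8-connected pixel lattice with
#' transition weights `tau^alpha * eta^beta`; the heuristic should dominate
#' the trail (`beta > alpha`). Pheromone is frozen during the `n_local` local
#' iterations of each round (selective updating); at each of the `n_global`
#' global updates the best tour of the round is reinforced at rate `rho` and
#' all other pixels evaporate at rate `phi`.
#'
#' @param alpha pheromone exponent (default 1).
#' @param beta heuristic exponent (default 2; must exceed `alpha`).
#' @param tau0 initial pheromone (default 1e-6, clamped up to `tau_min`).
#' @param phi evaporation rate off the best tour (default 0.2).
#' @param rho best-tour reinforcement rate (default 0.3).
#' @param tau_min,tau_max pheromone bounds (defaults 0.001 and 0.999).
#' @param n_ants ants per local iteration; default `ceiling(sqrt(pixels))`.
#' @param n_steps moves per tour (default 40).
#' @param n_local local iterations per global update (default 4).
#' @param n_global global updates (default 10).
#' @param seed optional RNG seed for a reproducible field.
#' @return A named list of class `aco_params`.
#' @export
aco_params <- function(alpha = 1, beta = 2, tau0 = 1e-6, phi = 0.2,
                       rho = 0.3, tau_min = 0.001, tau_max = 0.999,
                       n_ants = NULL, n_steps = 40, n_local = 4,
                       n_global = 10, seed = NULL) {
  if (phi <= 0 || phi >= 1 || rho <= 0 || rho >= 1)
    stop("phi and rho must lie strictly between 0 and 1")
  if (tau_min >= tau_max) stop("tau_min must be below tau_max")
  if (beta <= alpha) stop("beta must exceed alpha (heuristic dominates)")
  if (n_steps <= 0) stop("n_steps must be positive")
  if (!is.null(n_ants) && n_ants <= 0) stop("n_ants must be positive")
  structure(list(alpha = alpha, beta = beta, tau0 = tau0, phi = phi,
                 rho = rho, tau_min = tau_min, tau_max = tau_max,
                 n_ants = n_ants, n_steps = n_steps, n_local = n_local,
                 n_global = n_global, seed = seed),
            class = "aco_params")
}

#' Heuristic field from an enhanced slice
#'
#' Per-pixel maximum of the absolute differences over the four symmetric
#' pixel pairs of the 3x3 neighbourhood (horizontal, vertical, two
#' diagonals), normalized by the global maximum (zero for a constant slice).
#'
#' @param slice 2D numeric matrix (at least 3x3).
#' @return Matrix of heuristic values in `[0, 1]`.
#' @export
heuristic_field <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < 3 || nc < 3) stop("heuristic field needs a slice of at least 3x3")
  idx <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  s <- function(dr, dc) slice[idx(nr, dr), idx(nc, dc)]
  eta <- pmax(
    abs(s(-1, 0) - s(1, 0)),
    abs(s(0, -1) - s(0, 1)),
    abs(s(-1, -1) - s(1, 1)),
    abs(s(-1, 1) - s(1, -1))
  )
  mx <- max(eta)
  if (mx > 0) eta / mx else eta
}

#' Run the variant ant-colony engine on one slice
#'
#' Initializes the pheromone field at `tau0` (clamped to the bounds), then
#' alternates `n_local` pheromone-frozen local iterations of ant tours with a
#' global update that reinforces the pixels of the round's best tour (highest
#' mean heuristic along the tour; ties keep the first found; no
#' reinforcement when the best tour carries zero heuristic signal) and
#' evaporates all other pixels, clamping to `[tau_min, tau_max]` after every
#' update. Deterministic for a fixed `seed`.
#'
#' @param slice enhanced slice (2D matrix); its [heuristic_field] drives the
#'   ants.
#' @param params an [aco_params] list.
#' @param trace if `TRUE`, also return the pheromone field snapshot after
#'   every local iteration and every global update (for invariant checks).
#' @return Matrix `tau` of pheromone values, or (with `trace = TRUE`) a list
#'   `tau`, `snapshots`, `stages`.
#' @export
run_variant_aco <- function(slice, params = aco_params(), trace = FALSE) {
  if (!inherits(params, "aco_params")) params <- do.call(aco_params, params)
  if (length(slice) == 0) stop("empty slice")
  eta <- heuristic_field(slice)
  n_ants <- params$n_ants
  if (is.null(n_ants)) n_ants <- ceiling(sqrt(length(slice)))
  if (!is.null(params$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(params$seed)
  }
  res <- .aco_cpp(eta, params$alpha, params$beta, params$tau0, params$phi,
                  params$rho, params$tau_min, params$tau_max,
                  as.integer(n_ants), as.integer(params$n_steps),
                  as.integer(params$n_local), as.integer(params$n_global),
                  isTRUE(trace))
  if (isTRUE(trace)) res else res$tau
}

#' Swarm boundary factor
#'
#' `B = 1 - tau` per pixel: high pheromone (confident boundary) makes the
#' boundary term cheap, so the cut prefers to run along detected edges.
#'
#' @param tau pheromone field (matrix or array).
#' @return `1 - tau`, elementwise.
#' @export
boundary_factor <- function(tau) 1 - tau

#' Per-edge pheromone from per-pixel fields
#'
#' The pheromone is defined per pixel but the energy needs per-edge values:
#' an in-slice 6-neighbour edge takes the maximum of its two endpoint values,
#' an inter-slice edge the mean of the two voxels' values on their respective
#' slices.
#'
#' @param tau 3D pheromone array (slice, row, column).
#' @param u,v voxel index triples `c(slice, row, col)` of 6-neighbours.
#' @return Scalar pheromone for the edge.
#' @export
edge_tau <- function(tau, u, v) {
  if (sum(abs(u - v)) != 1L) stop("u and v must be 6-neighbours")
  tu <- tau[u[1], u[2], u[3]]; tv <- tau[v[1], v[2], v[3]]
  if (u[1] == v[1]) max(tu, tv) else (tu + tv) / 2
}

#' Pheromone fields for every slice of a volume
#'
#' @param enhanced 3D enhanced image (slice, row, column).
#' @param params an [aco_params] list; when `params$seed` is set the whole
#'   stack is reproducible (one RNG stream across slices).
#' @return 3D array of pheromone values.
#' @export
aco_stack <- function(enhanced, params = aco_params()) {
  if (!inherits(params, "aco_params")) params <- do.call(aco_params, params)
  d <- dim(enhanced)
  if (!is.null(params$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(params$seed)
  }
  slice_params <- params
  slice_params$seed <- NULL
  tau <- array(0, d)
  for (k in seq_len(d[1]))
    tau[k, , ] <- run_variant_aco(enhanced[k, , ], slice_params)
  tau
}
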