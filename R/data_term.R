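# Domain-knowledge data term: an HU-interval intensity prior combined with a
# path-connectivity likelihood expanded from the user seeds, converted to
# -log terminal capacities.

#' Liver intensity interval prior
#'
#' The HU interval \[`hu_low`, `hu_high`\] in which liver parenchyma is
#' expected. The normalized parabola over this interval drives the intensity
#' weight: values in the central confident band are damped with exponent `q`,
#' while the dubitable margins (normalized value below `theta`) keep weight 1.
#'
#' @param hu_low,hu_high interval bounds in HU (`hu_low < hu_high`).
#' @param theta dubitable-band parameter, default `(1/7) * (6/7) = 6/49`; must
#'   lie in (0, 1/4), the range of the normalized parabola.
#' @param q exponent constant, default -4 (negative so the confident band
#'   reduces the intensity-difference penalty).
#' @return An object of class `intensity_interval`.
#' @export
intensity_interval <- function(hu_low, hu_high, theta = 6 / 49, q = -4) {
  if (!is.finite(hu_low) || !is.finite(hu_high) || hu_low >= hu_high)
    stop("intensity interval requires hu_low < hu_high")
  if (theta <= 0 || theta >= 0.25)
    stop("theta must lie strictly between 0 and 1/4")
  structure(list(hu_low = hu_low, hu_high = hu_high, theta = theta, q = q),
            class = "intensity_interval")
}

#' Estimate the liver HU interval from object seeds
#'
#' Sharp bounds for the parenchyma interval are hard to fix a priori, so by
#' default they are estimated as mean +/- 3 sd of the object-seed intensities.
#'
#' @param volume a [ct_volume].
#' @param seeds a [seed_set].
#' @inheritParams intensity_interval
#' @return An `intensity_interval`.
#' @export
estimate_interval <- function(volume, seeds, theta = 6 / 49, q = -4) {
  vals <- volume$intensities[seeds$object_mask]
  if (length(vals) == 0) stop("no object seeds to estimate the HU interval")
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) s <- 1
  intensity_interval(mean(vals) - 3 * s, mean(vals) + 3 * s,
                     theta = theta, q = q)
}

#' Normalized interval position
#'
#' `(I - low)(high - I) / (high - low)^2`, clamped to \[0, 1/4\] inside the
#' interval and 0 outside: the unit-free parabola whose value `theta = 6/49`
#' is reached exactly at fractional positions 1/7 and 6/7 of the interval.
#'
#' @param intensity HU value(s).
#' @param interval an [intensity_interval].
#' @return Values in \[0, 1/4\].
#' @export
normalized_intensity <- function(intensity, interval) {
  lo <- interval$hu_low; hi <- interval$hu_high
  x <- (intensity - lo) * (hi - intensity) / (hi - lo)^2
  x[intensity < lo | intensity > hi] <- 0
  pmin(pmax(x, 0), 0.25)
}

#' Intensity weight
#'
#' Weight 1 on the dubitable margins (`0 < normalized < theta`) and
#' `exp(q * normalized)` elsewhere; with `q < 0` the confident central band
#' damps the intensity-difference penalty of the connectivity likelihood,
#' letting the expansion jump over false edges inside liver tissue.
#'
#' @inheritParams normalized_intensity
#' @return Weight value(s) in (0, 1\].
#' @export
intensity_weight <- function(intensity, interval) {
  x <- normalized_intensity(intensity, interval)
  ifelse(x > 0 & x < interval$theta, 1, exp(interval$q * x))
}

#' Path-connectivity likelihood by seeded expansion
#'
#' Best-first expansion over the 6-connected lattice from the seed voxels.
#' A voxel reached from an already-expanded neighbour receives the candidate
#' likelihood
#' `exp(-Iw * mu * (Int - IntBar_prev)^2 / (step_mm + Dis_prev))`, the maximum
#' over incoming offers is kept, and on acceptance the running mean intensity
#' and the aggregate path distance are updated
#' (`IntBar = (Int + IntBar_prev)/2`, `Dis = step_mm + Dis_prev`). Seeds carry
#' likelihood 1, path distance `delta_dis` and their own intensity. Each voxel
#' is finalized once, in order of decreasing current likelihood with
#' lexicographic tie-breaks, so the result is reproducible and independent of
#' seed insertion order.
#'
#' @param volume a [ct_volume].
#' @param seed_mask logical array of seed voxels (non-empty).
#' @param mu expansion scale (object default 12, background default 8).
#' @param interval an [intensity_interval] supplying the per-voxel intensity
#'   weight, or `NULL` for weight 1 (background expansion).
#' @param delta_dis seed path-distance offset in mm (default 1), keeping the
#'   first-step denominator positive.
#' @param eps_floor minimum likelihood (default 1e-6).
#' @return Numeric array of likelihoods in `[eps_floor, 1]`.
#' @export
propagate_likelihood <- function(volume, seed_mask, mu, interval = NULL,
                                 delta_dis = 1, eps_floor = 1e-6) {
  if (mu <= 0) stop("mu must be positive")
  if (eps_floor <= 0 || eps_floor >= 1)
    stop("eps_floor must lie strictly between 0 and 1")
  seeds <- which(seed_mask) - 1L
  if (length(seeds) == 0) stop("empty seed set")
  iw <- if (is.null(interval)) 1.0 else
    as.numeric(intensity_weight(volume$intensities, interval))
  d <- vol_dim(volume)
  .propagate_cpp(as.numeric(volume$intensities), as.integer(d),
                 as.integer(seeds), iw, as.numeric(volume$spacing),
                 mu, delta_dis, eps_floor)
}

#' Object and background likelihood fields
#'
#' @param volume a [ct_volume].
#' @param seeds a [seed_set].
#' @param mu1,mu2 object/background expansion scales (defaults 12 and 8).
#' @param interval an [intensity_interval], or `NULL` to estimate it from the
#'   object seeds; the interval weight applies to the object expansion only.
#' @param use_intensity_weight set `FALSE` to disable the interval weight
#'   (plain-connectivity baseline).
#' @inheritParams propagate_likelihood
#' @return List with `pr_object`, `pr_background` (arrays in
#'   `[eps_floor, 1]`, equal to 1 on their own seeds) and the `interval` used.
#' @export
likelihood_field <- function(volume, seeds, mu1 = 12, mu2 = 8,
                             interval = NULL, use_intensity_weight = TRUE,
                             delta_dis = 1, eps_floor = 1e-6) {
  check_seeds_usable(seeds)
  if (is.null(interval)) interval <- estimate_interval(volume, seeds)
  obj_int <- if (use_intensity_weight) interval else NULL
  list(
    pr_object = propagate_likelihood(volume, seeds$object_mask, mu1,
                                     interval = obj_int,
                                     delta_dis = delta_dis,
                                     eps_floor = eps_floor),
    pr_background = propagate_likelihood(volume, seeds$background_mask, mu2,
                                         interval = NULL,
                                         delta_dis = delta_dis,
                                         eps_floor = eps_floor),
    interval = interval
  )
}

#' Data cost
#'
#' `-log` of the (floored) likelihood: 0 where the likelihood is 1, at most
#' `-log(eps_floor)` everywhere, always finite.
#'
#' @param likelihood likelihood value(s) in (0, 1\].
#' @param eps_floor minimum likelihood before taking the log.
#' @return Nonnegative cost value(s).
#' @export
data_cost <- function(likelihood, eps_floor = 1e-6) {
  -log(pmin(pmax(likelihood, eps_floor), 1))
}
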