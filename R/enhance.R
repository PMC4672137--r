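# ROI-based enhancement: per-slice local appearance profiles (intensity and
# LBP histograms over a sliding window) are compared with a seed-derived
# global appearance model through the 1D Wasserstein distance, giving
# region-characteristic certainty fields whose sum highlights non-liver
# structure and weak boundaries.

#' Local binary pattern map with noise offset
#'
#' Per-pixel code `sum_t H(I_t - I_c - zeta) * 2^t`, where the `I_t` are
#' sampled (bilinear interpolation, edge replication at the borders) at `m`
#' equally spaced angles on a circle of radius `r`, indexed counter-clockwise
#' from angle 0, and `H` is the unit step. The offset `zeta` absorbs CT noise:
#' a neighbour must exceed the centre by more than `zeta` to set its bit.
#'
#' @param slice 2D numeric matrix (one axial slice).
#' @param m neighbour count (default 6; at least 4).
#' @param r circle radius in pixels (default 1).
#' @param zeta noise offset in HU (default 1.6, nonnegative).
#' @return Integer matrix of codes in `[0, 2^m - 1]`.
#' @export
lbp_map <- function(slice, m = 6, r = 1, zeta = 1.6) {
  if (m < 4) stop("lbp neighbour count m must be at least 4")
  if (r < 1) stop("lbp radius must be at least 1")
  if (zeta < 0) stop("zeta must be nonnegative")
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < 2 * r + 1 || nc < 2 * r + 1)
    stop("slice smaller than the LBP support (2r + 1 per side)")
  idx <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  code <- matrix(0L, nr, nc)
  for (t in seq_len(m) - 1) {
    ang <- 2 * pi * t / m
    dr <- -r * sin(ang)            # counter-clockwise in image coordinates
    dc <- r * cos(ang)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)  # exact axis samples
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    samp <- (1 - fr) * (1 - fc) * slice[idx(nr, r0), idx(nc, c0)] +
            (1 - fr) * fc       * slice[idx(nr, r0), idx(nc, c0 + 1)] +
            fr * (1 - fc)       * slice[idx(nr, r0 + 1), idx(nc, c0)] +
            fr * fc             * slice[idx(nr, r0 + 1), idx(nc, c0 + 1)]
    code <- code + bitwShiftL(1L, t) * (samp - slice - zeta >= 0)
  }
  code
}

# 2D inclusive prefix sums with a zero-padded first row/column.
cum2d_pad <- function(m) {
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(m))
  cs <- t(apply(cs, 1, cumsum))
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(m))
  rbind(0, cbind(0, cs))
}

#' Per-pixel local appearance profiles
#'
#' Normalized histogram of a feature image over an odd sliding window centred
#' at each pixel (truncated at the image border), computed with an integral
#' histogram so the cost is linear in pixels times bins.
#'
#' @param feature 2D numeric matrix (intensity slice or LBP code map).
#' @param window odd window side length, at least 3 (default 7).
#' @param breaks histogram bin edges (length `bins + 1`, strictly increasing).
#' @param values representative value per bin (default: bin midpoints); these
#'   are the support points of the Wasserstein comparison.
#' @return A `local_profiles` list: `prob` (array `nrow x ncol x bins`),
#'   `values`, `breaks`.
#' @export
local_profiles <- function(feature, window = 7, breaks,
                           values = (head(breaks, -1) + tail(breaks, -1)) / 2) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  nb <- length(breaks) - 1
  if (nb < 1 || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing bin edges")
  nr <- nrow(feature); nc <- ncol(feature)
  bin <- findInterval(feature, breaks, all.inside = TRUE)
  h <- (window - 1) %/% 2
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  prob <- array(0, c(nr, nc, nb))
  total <- matrix(0, nr, nc)
  for (b in seq_len(nb)) {
    P <- cum2d_pad(matrix(as.numeric(bin == b), nr, nc))
    cnt <- P[r2 + 1, c2 + 1, drop = FALSE] - P[r1, c2 + 1, drop = FALSE] -
           P[r2 + 1, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
    prob[, , b] <- cnt
    total <- total + cnt
  }
  for (b in seq_len(nb)) prob[, , b] <- prob[, , b] / total
  structure(list(prob = prob, values = as.numeric(values),
                 breaks = as.numeric(breaks)),
            class = "local_profiles")
}

profiles_matrix <- function(profiles) {
  d <- dim(profiles$prob)
  matrix(profiles$prob, nrow = d[1] * d[2], ncol = d[3])
}

#' First Wasserstein distance between two histograms
#'
#' `W1 = integral |F - G| dy` over the feature range, evaluated as the sum of
#' absolute CDF differences weighted by the gaps between consecutive support
#' points. Point masses at support values `a` and `b` give exactly `|a - b|`.
#'
#' @param p,q normalized histograms over the same support.
#' @param values common support points (sorted).
#' @return Nonnegative scalar.
#' @export
w1_distance <- function(p, q, values) {
  if (length(p) != length(q) || length(p) != length(values))
    stop("histograms and support must have matching lengths")
  if (length(values) == 1) return(0)
  dF <- cumsum(p - q)
  sum(abs(dF[-length(dF)]) * diff(values))
}

# rowwise W1 of an n x B probability matrix against a single reference q
w1_rows <- function(mat, q, values) {
  nb <- length(values)
  if (nb == 1) return(rep(0, nrow(mat)))
  dif <- sweep(mat, 2, q)
  cs <- dif
  for (b in 2:nb) cs[, b] <- cs[, b - 1] + dif[, b]
  as.numeric(abs(cs[, -nb, drop = FALSE]) %*% diff(values))
}

#' Global appearance model from seed pixels
#'
#' Element-wise mean of the seed-pixel profiles, with a scalar tolerable
#' appearance variance defined as the mean squared Wasserstein deviation of
#' the seed profiles from that mean, floored to keep the certainty field
#' finite on perfectly homogeneous seeds.
#'
#' @param profiles a `local_profiles` object (see [local_profiles]) or a
#'   matrix of profiles (rows = pixels).
#' @param seed_mask logical matrix selecting the seed pixels (ignored when
#'   `profiles` is already a matrix).
#' @param values support points (taken from `profiles` when available).
#' @param sigma_floor lower bound for the variance (default 1e-3).
#' @return A `global_appearance` list: `mean` profile, `sigma2` (floored
#'   variance), `values`.
#' @export
global_model <- function(profiles, seed_mask = NULL, values = NULL,
                         sigma_floor = 1e-3) {
  if (inherits(profiles, "local_profiles")) {
    if (is.null(seed_mask)) stop("seed_mask required with local_profiles")
    mat <- profiles_matrix(profiles)[as.vector(seed_mask), , drop = FALSE]
    values <- profiles$values
  } else {
    mat <- as.matrix(profiles)
  }
  if (nrow(mat) == 0) stop("no seed pixels to build the appearance model")
  if (is.null(values)) stop("support values required")
  m <- colMeans(mat)
  sigma2 <- mean(w1_rows(mat, m, values)^2)
  structure(list(mean = m, sigma2 = max(sigma2, sigma_floor),
                 values = as.numeric(values)),
            class = "global_appearance")
}

#' Region-characteristic certainty field for one feature
#'
#' Per-pixel `W1(local profile, global profile) / sigma^2`: near zero where
#' the neighbourhood looks like seeded liver, large where non-liver structure
#' dominates the window.
#'
#' @param profiles a `local_profiles` object.
#' @param model a `global_appearance` model over the same support.
#' @return Nonnegative numeric matrix.
#' @export
certainty_field <- function(profiles, model) {
  if (!isTRUE(all.equal(profiles$values, model$values)))
    stop("profile and model support points differ")
  d <- dim(profiles$prob)
  w1 <- w1_rows(profiles_matrix(profiles), model$mean, model$values)
  matrix(w1 / model$sigma2, d[1], d[2])
}

#' Parameters of the enhancement stage
#'
#' @param lbp_m,lbp_r,zeta LBP neighbour count, radius and noise offset
#'   (defaults 6, 1, 1.6 HU).
#' @param window local profile window (odd, default 7).
#' @param intensity_bins number of intensity histogram bins (default 32) over
#'   `[hu_low - 50, hu_high + 50]`.
#' @param sigma_floor appearance variance floor (default 1e-3).
#' @return A named list of parameters.
#' @export
enhance_params <- function(lbp_m = 6, lbp_r = 1, zeta = 1.6, window = 7,
                           intensity_bins = 32, sigma_floor = 1e-3) {
  list(lbp_m = lbp_m, lbp_r = lbp_r, zeta = zeta, window = window,
       intensity_bins = intensity_bins, sigma_floor = sigma_floor)
}

#' ROI-based enhanced image
#'
#' For every axial slice, computes intensity and LBP local profiles, builds
#' the seed-derived global appearance model per feature (pooling seed pixels
#' over all slices), forms the two certainty fields, and returns their sum
#' rescaled to `[0, 1]` per slice. This enhanced image is the input of the
#' variant ant-colony boundary detector.
#'
#' @param volume a [ct_volume].
#' @param seeds a [seed_set] with at least one object seed.
#' @param params list from [enhance_params].
#' @param interval an [intensity_interval] fixing the intensity bin range, or
#'   `NULL` to estimate it from the object seeds.
#' @return List with `enhanced` (3D array in `[0, 1]`), the feature `models`,
#'   and the `interval` used.
#' @export
enhanced_image <- function(volume, seeds, params = enhance_params(),
                           interval = NULL) {
  if (!any(seeds$object_mask)) stop("enhancement requires object seeds")
  if (is.null(interval)) interval <- estimate_interval(volume, seeds)
  d <- vol_dim(volume)
  int_breaks <- seq(interval$hu_low - 50, interval$hu_high + 50,
                    length.out = params$intensity_bins + 1)
  ncodes <- 2^params$lbp_m
  lbp_breaks <- seq(-0.5, ncodes - 0.5, by = 1)
  lbp_values <- 0:(ncodes - 1)

  slice_profiles <- function(k) {
    sl <- volume$intensities[k, , ]
    list(
      int = local_profiles(sl, params$window, int_breaks),
      lbp = local_profiles(lbp_map(sl, params$lbp_m, params$lbp_r,
                                   params$zeta),
                           params$window, lbp_breaks, values = lbp_values)
    )
  }

  # pass 1: pool seed-pixel profiles into the global model per feature
  seed_rows <- list(int = NULL, lbp = NULL)
  for (k in seq_len(d[1])) {
    sm <- seeds$object_mask[k, , ]
    if (!any(sm)) next
    pr <- slice_profiles(k)
    seed_rows$int <- rbind(seed_rows$int,
                           profiles_matrix(pr$int)[as.vector(sm), ,
                                                   drop = FALSE])
    seed_rows$lbp <- rbind(seed_rows$lbp,
                           profiles_matrix(pr$lbp)[as.vector(sm), ,
                                                   drop = FALSE])
  }
  if (is.null(seed_rows$int)) stop("object seeds present on no slice")
  int_values <- (head(int_breaks, -1) + tail(int_breaks, -1)) / 2
  models <- list(
    int = global_model(seed_rows$int, values = int_values,
                       sigma_floor = params$sigma_floor),
    lbp = global_model(seed_rows$lbp, values = lbp_values,
                       sigma_floor = params$sigma_floor)
  )

  # pass 2: certainty fields and per-slice rescaled sum
  enhanced <- array(0, d)
  for (k in seq_len(d[1])) {
    pr <- slice_profiles(k)
    cc <- certainty_field(pr$int, models$int) +
          certainty_field(pr$lbp, models$lbp)
    mx <- max(cc)
    enhanced[k, , ] <- if (mx > 0) cc / mx else cc
  }
  list(enhanced = enhanced, models = models, interval = interval)
}
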