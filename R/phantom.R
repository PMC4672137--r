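# Deterministic synthetic abdominal phantom: a lobed liver ellipsoid with
# bright internal vessels, an adjacent organ sharing a boundary with a
# configurable HU offset (0 emulates the iso-intense "special slice" regime),
# optional posterior bone cylinder, Gaussian boundary blur and additive noise.
# Provides ground truth and auto-placed seeds for end-to-end tests.

#' Phantom specification
#'
#' @param dim grid size (slice, row, column), default 64^3.
#' @param spacing voxel spacing in mm, default isotropic 1 mm.
#' @param delta HU offset of the adjacent organ relative to liver (default
#'   60; 0-5 gives the nearly iso-intense boundary regime).
#' @param blur Gaussian boundary blur sigma in mm (default 1).
#' @param noise additive Gaussian noise sd in HU (default 10).
#' @param vessels include bright tubes inside the liver (default `TRUE`).
#' @param bone include a posterior bone cylinder (for crossline detection
#'   tests; default `FALSE`).
#' @param hu HU palette: liver 110, vessel 180, background 40, bone 700.
#' @param seed RNG seed making the phantom deterministic (default 1).
#' @return A named list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 64), spacing = c(1, 1, 1),
                         delta = 60, blur = 1, noise = 10, vessels = TRUE,
                         bone = FALSE,
                         hu = list(liver = 110, vessel = 180,
                                   background = 40, bone = 700),
                         seed = 1) {
  if (length(dim) != 3 || any(dim < 16))
    stop("phantom grid must be 3D with at least 16 voxels per axis")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 delta = delta, blur = blur, noise = noise,
                 vessels = vessels, bone = bone, hu = hu, seed = seed),
            class = "phantom_spec")
}

ellipsoid_mask <- function(d, center, semi) {
  s <- slice.index(array(0, d), 1)
  r <- slice.index(array(0, d), 2)
  c <- slice.index(array(0, d), 3)
  ((s - center[1]) / semi[1])^2 + ((r - center[2]) / semi[2])^2 +
    ((c - center[3]) / semi[3])^2 <= 1
}

# separable Gaussian blur with edge replication
gauss_blur3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- dnorm(-h:h, sd = s)
    k <- k / sum(k)
    arr <- apply_along(arr, ax, function(x) {
      n <- length(x)
      xp <- c(rep(x[1], h), x, rep(x[n], h))
      as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(h + n)]
    })
  }
  arr
}

apply_along <- function(arr, axis, f) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  m <- apply(m, 2, f)
  out <- array(m, d[perm])
  aperm(out, order(perm))
}

dilate6 <- function(mask, k) {
  d <- dim(mask)
  for (i in seq_len(k)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

erode6 <- function(mask, k) {
  d <- dim(mask)
  for (i in seq_len(k)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] & mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] & mask[-1, , ]
    m[, -1, ] <- m[, -1, ] & mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] & mask[, -1, ]
    m[, , -1] <- m[, , -1] & mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] & mask[, , -1]
    m[1, , ] <- FALSE; m[d[1], , ] <- FALSE
    m[, 1, ] <- FALSE; m[, d[2], ] <- FALSE
    m[, , 1] <- FALSE; m[, , d[3]] <- FALSE
    mask <- m
  }
  mask
}

#' Generate a synthetic abdominal phantom
#'
#' Deterministic for a fixed `spec$seed`. Object seeds are an eroded core of
#' the liver (including any vessels inside it); background seeds sit inside
#' the adjacent organ - the most ambiguous boundary - and in the far
#' background.
#'
#' @param spec a [phantom_spec].
#' @return List with `volume` (a [ct_volume]), `truth` (a
#'   [segmentation_mask] of the liver) and `seeds` (a [seed_set]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$dim
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  center <- d * c(0.5, 0.45, 0.40)
  liver <- ellipsoid_mask(d, center, d * c(0.32, 0.26, 0.24)) |
    ellipsoid_mask(d, d * c(0.42, 0.58, 0.52), d * c(0.20, 0.14, 0.13))
  organ_region <- ellipsoid_mask(d, d * c(0.5, 0.42, 0.78),
                                 d * c(0.24, 0.18, 0.17))
  organ <- organ_region & !liver
  if (!any(liver) || !any(organ))
    stop("degenerate phantom geometry: empty liver or adjacent organ")

  vol <- array(spec$hu$background, d)
  vol[liver] <- spec$hu$liver
  vol[organ] <- spec$hu$liver + spec$delta
  vessel <- array(FALSE, d)
  if (isTRUE(spec$vessels)) {
    r <- slice.index(vol, 2); c <- slice.index(vol, 3)
    for (off in list(c(0, 0), c(-0.08, 0.06))) {
      cc <- d[2:3] * (c(0.45, 0.40) + off)
      tube <- (r - cc[1])^2 + (c - cc[2])^2 <= (0.03 * d[2])^2
      vessel <- vessel | (tube & liver)
    }
    vol[vessel] <- spec$hu$vessel
  }
  if (isTRUE(spec$bone)) {
    r <- slice.index(vol, 2); c <- slice.index(vol, 3)
    bc <- c(0.85 * d[2], 0.5 * d[3])
    tube <- (r - bc[1])^2 + (c - bc[2])^2 <= (0.04 * d[2])^2
    vol[tube] <- spec$hu$bone
  }
  # acquisition noise enters before the reconstruction blur, giving the
  # spatially correlated noise of real CT; with blur = 0 the noise is white
  if (spec$noise > 0) vol <- vol + rnorm(length(vol), sd = spec$noise)
  if (spec$blur > 0) vol <- gauss_blur3(vol, spec$blur / spec$spacing)

  # seeds mimic the interactive protocol: object scribbles well inside the
  # liver, background contours hugging the ambiguous boundary plus the
  # adjacent organ and the far field
  obj_seed <- erode6(liver, 2L)
  ring <- dilate6(liver, 3L) & !liver
  bg_organ <- erode6(organ, 1L) | ring
  bg_far <- array(FALSE, d)          # generous far-background marking:
  bg_far[c(1:2, d[1] - 1, d[1]), , ] <- TRUE   # a 2-voxel shell on every face
  bg_far[, c(1:2, d[2] - 1, d[2]), ] <- TRUE
  bg_far[, , c(1:2, d[3] - 1, d[3])] <- TRUE
  bg_seed <- (bg_organ | (bg_far & !organ_region)) & !liver
  if (!any(obj_seed) || !any(bg_seed))
    stop("degenerate phantom geometry: empty seed regions")

  list(volume = ct_volume(vol, spacing = spec$spacing),
       truth = segmentation_mask(liver, spacing = spec$spacing),
       seeds = seed_set(obj_seed, bg_seed))
}
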