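# Seed specification: per-slice closed polygons extruded over a slice range
# ("cylindrical" seeds), or ready-made label masks (0 unlabeled / 1 object /
# 2 background).

# Even-odd scanline fill of a closed polygon at pixel centres.
# vertices: n x 2 matrix of (row, col); returns logical nrow x ncol matrix.
polygon_fill <- function(vertices, nrow, ncol) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3)
    stop("polygon needs at least 3 (row, col) vertices")
  out <- matrix(FALSE, nrow, ncol)
  n <- nrow(v)
  r1 <- v[, 1]; c1 <- v[, 2]
  r2 <- v[c(2:n, 1), 1]; c2 <- v[c(2:n, 1), 2]
  for (r in seq_len(nrow)) {
    # half-open rule [min, max) avoids double-counting shared vertices
    hit <- (pmin(r1, r2) <= r) & (r < pmax(r1, r2))
    if (!any(hit)) {
      flat <- (r1 == r) & (r2 == r)   # horizontal edge lying on the scanline
      if (any(flat))
        for (k in which(flat)) {
          cc <- seq(ceiling(min(c1[k], c2[k])), floor(max(c1[k], c2[k])))
          cc <- cc[cc >= 1 & cc <= ncol]
          out[r, cc] <- TRUE
        }
      next
    }
    xs <- c1[hit] + (r - r1[hit]) * (c2[hit] - c1[hit]) / (r2[hit] - r1[hit])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      cc <- seq(ceiling(xs[k]), floor(xs[k + 1]))
      cc <- cc[cc >= 1 & cc <= ncol]
      out[r, cc] <- TRUE
    }
  }
  out
}

#' Rasterize seed contours into a seed set
#'
#' Each contour is a closed polygon drawn on the axial plane and extruded over
#' a contiguous slice range, giving the cylindrical seed regions of the
#' interactive initialization. Object and background regions must not
#' intersect.
#'
#' @param contours list of contour specs, each a list with elements `label`
#'   (`"object"` or `"background"`), `slices` (length-2 start/end slice
#'   indices, inclusive), and `vertices` (n x 2 matrix of (row, col) polygon
#'   vertices, closed implicitly).
#' @param volume the [ct_volume] the seeds refer to.
#' @return A [seed_set].
#' @export
rasterize_seeds <- function(contours, volume) {
  d <- vol_dim(volume)
  obj <- array(FALSE, d); bg <- array(FALSE, d)
  if (length(contours) == 0) stop("no contours supplied")
  for (ct in contours) {
    if (is.null(ct$label) || !ct$label %in% c("object", "background"))
      stop("contour label must be 'object' or 'background'")
    sl <- as.integer(ct$slices)
    if (length(sl) == 1) sl <- c(sl, sl)
    if (length(sl) != 2 || sl[1] > sl[2] || sl[1] < 1 || sl[2] > d[1])
      stop("contour slice range out of volume bounds")
    v <- as.matrix(ct$vertices)
    if (any(v[, 1] < 1 | v[, 1] > d[2] | v[, 2] < 1 | v[, 2] > d[3]))
      stop("contour polygon extends outside the image grid")
    fill <- polygon_fill(v, d[2], d[3])
    if (!any(fill)) stop("contour polygon encloses no pixel centres")
    for (k in sl[1]:sl[2]) {
      if (ct$label == "object") obj[k, , ] <- obj[k, , ] | fill
      else bg[k, , ] <- bg[k, , ] | fill
    }
  }
  if (!any(obj)) stop("no object seed voxels rasterized")
  if (!any(bg)) stop("no background seed voxels rasterized")
  seed_set(obj, bg)  # errors if object and background overlap
}

#' Read seed contours from a YAML file
#'
#' The file holds a list of contours, each with `label`, `slices`
#' (start/end), and `vertices` (list of `[row, col]` pairs).
#'
#' @param path YAML file path.
#' @return A contour list suitable for [rasterize_seeds].
#' @export
read_seed_contours <- function(path) {
  if (!file.exists(path)) stop("seed contour file not found: ", path)
  spec <- yaml::read_yaml(path)
  lapply(spec, function(ct) {
    ct$vertices <- do.call(rbind, lapply(ct$vertices, as.numeric))
    ct$slices <- as.integer(unlist(ct$slices))
    ct
  })
}

#' Build a seed set from a label volume
#'
#' Accepts a label array or a volume file with values 0 (unlabeled),
#' 1 (object) and 2 (background), the scripted-test alternative to drawing
#' contours.
#'
#' @param labels a 3D array or a file path readable by [read_volume].
#' @return A [seed_set].
#' @export
seeds_from_labels <- function(labels) {
  if (is.character(labels)) labels <- read_volume(labels)$intensities
  labels <- round(labels)
  if (!all(labels %in% c(0, 1, 2)))
    stop("seed label volume must contain only 0, 1, 2")
  seed_set(labels == 1, labels == 2)
}
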