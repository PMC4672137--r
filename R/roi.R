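# Region-of-interest reduction: bounding-box cropping and spine-crossline
# quadrant elimination, applied before graph construction to shrink the
# computing space.

#' Crop a volume to an inclusive bounding box
#'
#' The offset of the crop is recorded so results can be re-embedded into the
#' original coordinates with [embed_mask].
#'
#' @param volume a [ct_volume].
#' @param bbox list or 3x2 matrix of inclusive index ranges per axis
#'   (slice, row, column), 1-based.
#' @return A [ct_volume] with attribute `offset` (1-based start indices) and
#'   `full_dim` (original grid dimension).
#' @export
crop_bbox <- function(volume, bbox) {
  d <- vol_dim(volume)
  b <- bbox_matrix(bbox)
  if (any(b[, 1] > b[, 2])) stop("empty bounding box")
  if (any(b[, 1] < 1) || any(b[, 2] > d)) stop("bounding box outside volume")
  sub <- volume$intensities[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2],
                            b[3, 1]:b[3, 2], drop = FALSE]
  out <- ct_volume(sub, spacing = volume$spacing,
                   origin = volume$origin + (b[, 1] - 1) * volume$spacing)
  attr(out, "offset") <- b[, 1]
  attr(out, "full_dim") <- d
  out
}

bbox_matrix <- function(bbox) {
  if (is.list(bbox)) bbox <- do.call(rbind, bbox)
  b <- matrix(as.integer(bbox), nrow = 3, ncol = 2)
  b
}

#' Re-embed a cropped mask into the original grid
#'
#' @param mask a [segmentation_mask] (or logical array) on the cropped grid.
#' @param offset 1-based start indices of the crop (from [crop_bbox]).
#' @param full_dim dimension of the original grid.
#' @param fill value for voxels outside the crop (default `FALSE`,
#'   i.e. background).
#' @return A [segmentation_mask] on the original grid.
#' @export
embed_mask <- function(mask, offset, full_dim, fill = FALSE) {
  spacing <- if (inherits(mask, "segmentation_mask")) mask$spacing else
    c(1, 1, 1)
  labels <- as_mask_array(mask)
  d <- dim(labels)
  out <- array(fill, full_dim)
  out[offset[1]:(offset[1] + d[1] - 1),
      offset[2]:(offset[2] + d[2] - 1),
      offset[3]:(offset[3] + d[3] - 1)] <- labels
  segmentation_mask(out, spacing = spacing)
}

#' Tight bounding box around seeds with a physical margin
#'
#' Scripted-run alternative to an interactively drawn box: the tight index box
#' around all seed voxels, dilated by `margin_mm` per axis and clipped to the
#' grid.
#'
#' @param seeds a [seed_set].
#' @param volume the corresponding [ct_volume].
#' @param margin_mm dilation margin in mm (default 30).
#' @return A 3x2 matrix of inclusive index ranges.
#' @export
auto_bbox <- function(seeds, volume, margin_mm = 30) {
  any_seed <- seeds$object_mask | seeds$background_mask
  if (!any(any_seed)) stop("seed set is empty")
  idx <- which(any_seed, arr.ind = TRUE)
  pad <- ceiling(margin_mm / volume$spacing)
  d <- vol_dim(volume)
  b <- rbind(
    c(max(1L, min(idx[, 1]) - pad[1]), min(d[1], max(idx[, 1]) + pad[1])),
    c(max(1L, min(idx[, 2]) - pad[2]), min(d[2], max(idx[, 2]) + pad[2])),
    c(max(1L, min(idx[, 3]) - pad[3]), min(d[3], max(idx[, 3]) + pad[3]))
  )
  storage.mode(b) <- "integer"
  b
}

#' Locate the spine crossline
#'
#' Returns the centroid (row, column) of supra-threshold (bone) voxels
#' restricted to the posterior half of the middle slice. Increasing row is
#' posterior in the assumed axial layout.
#'
#' @param volume a [ct_volume].
#' @param bone_threshold HU threshold separating bone from contrast-enhanced
#'   soft tissue (default 200).
#' @return An object of class `crossline` with field `center = c(row, col)`.
#' @export
detect_crossline <- function(volume, bone_threshold = 200) {
  d <- vol_dim(volume)
  mid <- volume$intensities[ceiling(d[1] / 2), , ]
  post <- mid[(floor(d[2] / 2) + 1):d[2], , drop = FALSE]
  hit <- which(post > bone_threshold, arr.ind = TRUE)
  if (nrow(hit) == 0)
    stop("no bone voxels above ", bone_threshold,
         " HU in the posterior half of the mid slice; ",
         "supply the crossline manually")
  center <- c(round(mean(hit[, 1])) + floor(d[2] / 2), round(mean(hit[, 2])))
  structure(list(center = as.integer(center)), class = "crossline")
}

#' @export
print.crossline <- function(x, ...) {
  cat(sprintf("<crossline> center (row, col) = (%d, %d)\n",
              x$center[1], x$center[2]))
  invisible(x)
}

#' Quadrant exclusion mask from a crossline
#'
#' Marks the voxels in one axial quadrant of the crossline (default
#' right-bottom: `row >= center row` and `col >= center col`) on every slice.
#' Excluded voxels later receive hard background terminal links.
#'
#' @param volume a [ct_volume].
#' @param crossline a `crossline` (see [detect_crossline]) or `c(row, col)`.
#' @param quadrant which quadrant to exclude (patient orientation varies);
#'   one of `"right-bottom"`, `"left-bottom"`, `"right-top"`, `"left-top"`.
#' @return Logical array, `TRUE` = excluded.
#' @export
eliminate_quadrant <- function(volume, crossline,
                               quadrant = c("right-bottom", "left-bottom",
                                            "right-top", "left-top")) {
  quadrant <- match.arg(quadrant)
  center <- if (inherits(crossline, "crossline")) crossline$center
            else as.integer(crossline)
  d <- vol_dim(volume)
  if (center[1] < 1 || center[1] > d[2] || center[2] < 1 || center[2] > d[3])
    stop("crossline center outside the grid")
  rows <- seq_len(d[2]); cols <- seq_len(d[3])
  rhit <- if (grepl("bottom", quadrant)) rows >= center[1] else
    rows <= center[1]
  chit <- if (grepl("right", quadrant)) cols >= center[2] else
    cols <= center[2]
  plane <- outer(rhit, chit, `&`)
  out <- array(FALSE, d)
  for (k in seq_len(d[1])) out[k, , ] <- plane
  out
}

check_roi_keeps_seeds <- function(seeds, exclusion = NULL, bbox = NULL,
                                  full_dim = NULL) {
  obj <- seeds$object_mask
  if (!is.null(bbox)) {
    b <- bbox_matrix(bbox)
    keep <- array(FALSE, dim(obj))
    keep[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]] <- TRUE
    if (any(obj & !keep))
      stop("bounding box would remove object seed voxels; seeds are ground truth")
  }
  if (!is.null(exclusion) && any(obj & exclusion))
    stop("quadrant elimination would remove object seed voxels; ",
         "seeds are ground truth")
  invisible(TRUE)
}
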