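#' CT volume container
#'
#' A 3D scalar grid of Hounsfield intensities with physical voxel spacing and
#' origin. The axis order is fixed as (slice, row, column); all physical
#' distances in the package are computed in millimetres from `spacing`.
#'
#' @param intensities 3D numeric array, dimension (slice, row, column), HU.
#' @param spacing numeric length-3, voxel size in mm per axis (slice, row,
#'   column); all components strictly positive.
#' @param origin numeric length-3, physical offset in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) == 0L)) stop("intensity grid is empty")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(
    list(intensities = intensities, spacing = spacing,
         origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (slice x row x col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm; HU range [%.1f, %.1f]\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

vol_dim <- function(volume) dim(volume$intensities)

#' Object/background seed container
#'
#' Disjoint boolean grids marking user-selected object (liver) and background
#' voxels. Seeds act as hard constraints in the cut and as anchors for the
#' path-connectivity likelihoods.
#'
#' @param object_mask,background_mask logical 3D arrays of identical dimension.
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(object_mask, background_mask) {
  if (!identical(dim(object_mask), dim(background_mask)))
    stop("seed masks must have identical dimensions")
  if (length(dim(object_mask)) != 3L) stop("seed masks must be 3D arrays")
  storage.mode(object_mask) <- "logical"
  storage.mode(background_mask) <- "logical"
  if (any(object_mask & background_mask))
    stop("object and background seeds overlap (O intersect B must be empty)")
  structure(list(object_mask = object_mask, background_mask = background_mask),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d object, %d background seed voxels\n",
              sum(x$object_mask), sum(x$background_mask)))
  invisible(x)
}

check_seeds_usable <- function(seeds) {
  if (!inherits(seeds, "seed_set")) stop("seeds must be a seed_set")
  if (!any(seeds$object_mask)) stop("seed set has no object voxels")
  if (!any(seeds$background_mask)) stop("seed set has no background voxels")
  invisible(TRUE)
}

#' Binary segmentation result
#'
#' @param labels logical 3D array, `TRUE` = object (liver).
#' @param spacing voxel spacing in mm (slice, row, column), carried for the
#'   surface metrics.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(list(labels = labels, spacing = spacing),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s voxels, %d labelled object\n",
              paste(dim(x$labels), collapse = " x "), sum(x$labels)))
  invisible(x)
}

as_mask_array <- function(x) {
  if (inherits(x, "segmentation_mask")) return(x$labels)
  if (is.array(x) && (is.logical(x) || is.numeric(x))) {
    y <- x != 0
    dim(y) <- dim(x)
    return(y)
  }
  stop("expected a segmentation_mask or a 3D array")
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.mhd$", lp)) return("metaimage")
  if (dir.exists(path)) return("dicom-series")
  stop("cannot infer volume format from '", path, "'")
}

#' Read a CT volume
#'
#' Reads NIfTI (`.nii`/`.nii.gz`), MetaImage (`.mhd` + `.raw`) or a DICOM
#' series directory into a [ct_volume]. DICOM intensities are rescaled to HU
#' using the slope/intercept header fields at read time. Inconsistent slice
#' positions in a DICOM series produce a warning and the median slice distance
#' is used.
#'
#' @param path file (NIfTI/MetaImage header) or directory (DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"metaimage"`, `"dicom-series"`.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage",
                                         "dicom-series")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    "nifti" = read_nifti_volume(path),
    "metaimage" = read_metaimage(path),
    "dicom-series" = read_dicom_series(path)
  )
}

#' Write a CT volume
#'
#' @param volume a [ct_volume].
#' @param path destination (file for NIfTI/MetaImage, directory for a DICOM
#'   series).
#' @param format as in [read_volume] (`"auto"` infers from the extension).
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti",
                                                  "metaimage",
                                                  "dicom-series")) {
  format <- match.arg(format)
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  if (format == "auto") {
    lp <- tolower(path)
    format <- if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
      else if (grepl("\\.mhd$", lp)) "metaimage"
      else if (!grepl("\\.", basename(path))) "dicom-series"
      else stop("cannot infer volume format from '", path, "'")
  }
  switch(format,
    "nifti" = write_nifti_volume(volume, path),
    "metaimage" = write_metaimage(volume, path),
    "dicom-series" = write_dicom_series(volume, path)
  )
  invisible(path)
}

#' Write a segmentation mask
#'
#' Lossless round trip of the boolean grid and its spacing (NIfTI or
#' MetaImage; stored as 8-bit 0/1).
#'
#' @param mask a [segmentation_mask].
#' @param path destination path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "segmentation_mask"))
    stop("mask must be a segmentation_mask")
  lp <- tolower(path)
  vol <- ct_volume(array(as.numeric(mask$labels), dim(mask$labels)),
                   spacing = mask$spacing)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    write_nifti_volume(vol, path, datatype = "uint8")
  } else if (grepl("\\.mhd$", lp)) {
    write_metaimage(vol, path, element_type = "MET_UCHAR")
  } else {
    stop("unsupported mask extension for '", path,
         "' (use .nii, .nii.gz or .mhd)")
  }
  invisible(path)
}

#' Read a segmentation mask written by [write_mask]
#'
#' @param path mask file path.
#' @return A [segmentation_mask].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  segmentation_mask(vol$intensities != 0, spacing = vol$spacing)
}

## ---- NIfTI (via RNifti) ----------------------------------------------------

# internal (slice,row,col) <-> NIfTI (i=col, j=row, k=slice)
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI image in ", path)
  pd <- RNifti::pixdim(img)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]))
}

write_nifti_volume <- function(volume, path, datatype = "double") {
  arr <- aperm(volume$intensities, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

## ---- MetaImage (.mhd / .raw) -----------------------------------------------

# Plain-text MetaImage header plus raw little-endian voxel data, x fastest.
# No reader for this format exists in the R ecosystem used here, so a minimal
# one is provided; it covers the element types this package writes or is
# likely to meet (uchar/short/ushort/float/double).
read_metaimage <- function(path) {
  if (!file.exists(path)) stop("MetaImage header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(kv)))
    stop("malformed MetaImage header '", path, "': missing ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  if (as.integer(kv$NDims) != 3L) stop("only 3D MetaImage volumes supported")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])  # x y z
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- kv$ElementType
  spec <- switch(type,
    MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
    MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
    MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported MetaImage ElementType: ", type)
  )
  raw_path <- kv$ElementDataFile
  if (raw_path != "LOCAL" && !grepl("^(/|[A-Za-z]:)", raw_path))
    raw_path <- file.path(dirname(path), raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n)
    stop("MetaImage raw file '", raw_path, "' is truncated")
  arr <- array(as.numeric(vals), dim = dims)      # (x, y, z)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(spacing),
            origin = rev(origin))
}

write_metaimage <- function(volume, path, element_type = "MET_DOUBLE") {
  if (!grepl("\\.mhd$", tolower(path)))
    stop("MetaImage header path must end in .mhd: ", path)
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  raw_path <- file.path(dirname(path), raw_name)
  d <- vol_dim(volume)                            # (slice,row,col)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            volume$spacing[3], volume$spacing[2], volume$spacing[1]),
    sprintf("Offset = %.10g %.10g %.10g",
            volume$origin[3], volume$origin[2], volume$origin[1]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", raw_name)
  )
  ok <- tryCatch({
    writeLines(hdr, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write MetaImage header to '", path, "'")
  vals <- as.vector(aperm(volume$intensities, c(3, 2, 1)))
  con <- file(raw_path, "wb")
  on.exit(close(con))
  switch(element_type,
    MET_UCHAR = writeBin(as.integer(round(vals)), con, size = 1,
                         endian = "little"),
    MET_SHORT = writeBin(as.integer(round(vals)), con, size = 2,
                         endian = "little"),
    MET_FLOAT = writeBin(as.numeric(vals), con, size = 4, endian = "little"),
    MET_DOUBLE = writeBin(as.numeric(vals), con, size = 8, endian = "little"),
    stop("unsupported MetaImage ElementType: ", element_type)
  )
  invisible(path)
}
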