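# Minimal DICOM series support: uncompressed explicit-VR little-endian CT
# slices, one file per slice, 16-bit pixels with slope/intercept HU rescale.
# This is not a general DICOM implementation; it handles the geometry and
# intensity tags a CT segmentation pipeline needs and rejects anything else.

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

# VRs with 12-byte headers (2 reserved + 4-byte length) in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  out <- list()
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% LONG_VRS) {
        len <- u32(pos + 8L); vpos <- pos + 12L
      } else {
        len <- u16(pos + 6L); vpos <- pos + 8L
      }
    } else {  # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4L); vpos <- pos + 8L
    }
    if (len < 0 || vpos + len - 1L > n)
      stop("corrupt DICOM element at byte ", pos, " in ", path)
    val <- if (len > 0) raw[vpos:(vpos + len - 1L)] else raw(0)
    out[[dcm_tag(group, elem)]] <- list(vr = vr, value = val)
    pos <- vpos + len
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dcm_ds <- function(el) {
  s <- dcm_str(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", size = 2, signed = FALSE, endian = "little")
}

read_dicom_slice <- function(path) {
  els <- read_dicom_file(path)
  rows <- dcm_us(els[["0028,0010"]])
  cols <- dcm_us(els[["0028,0011"]])
  px <- els[["7FE0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("DICOM file lacks image data tags: ", path)
  bits <- dcm_us(els[["0028,0100"]])
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit DICOM pixel data supported: ", path)
  signed <- identical(dcm_us(els[["0028,0103"]]), 1L)
  vals <- readBin(px$value, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
  slope <- dcm_ds(els[["0028,1053"]]); if (is.null(slope)) slope <- 1
  inter <- dcm_ds(els[["0028,1052"]]); if (is.null(inter)) inter <- 0
  hu <- slope * vals + inter
  ps <- dcm_ds(els[["0028,0030"]])  # row spacing \ column spacing
  if (is.null(ps) || length(ps) != 2) ps <- c(1, 1)
  ipp <- dcm_ds(els[["0020,0032"]])
  z <- if (!is.null(ipp) && length(ipp) == 3) ipp[3] else
    dcm_ds(els[["0020,1041"]])
  if (is.null(z)) z <- NA_real_
  # DICOM pixel data is row-major (row by row)
  list(pixels = matrix(hu, nrow = rows, ncol = cols, byrow = TRUE),
       row_spacing = ps[1], col_spacing = ps[2], z = z)
}

read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("DICOM series directory not found: ", path)
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop("no DICOM files found in directory: ", path)
  slices <- lapply(sort(files), read_dicom_slice)
  rows <- unique(vapply(slices, function(s) nrow(s$pixels), 0L))
  cols <- unique(vapply(slices, function(s) ncol(s$pixels), 0L))
  if (length(rows) != 1 || length(cols) != 1)
    stop("DICOM series has inconsistent slice dimensions in ", path)
  z <- vapply(slices, function(s) s$z, 0.0)
  if (all(is.finite(z))) {
    ord <- order(z)
    slices <- slices[ord]
    z <- z[ord]
  }
  dz <- if (length(z) > 1 && all(is.finite(z))) diff(z) else 1
  slice_spacing <- stats::median(dz)
  if (length(unique(round(dz, 6))) > 1)
    warning("inconsistent slice spacing in DICOM series; using median (",
            signif(slice_spacing, 6), " mm)")
  if (!is.finite(slice_spacing) || slice_spacing <= 0) slice_spacing <- 1
  arr <- array(0, dim = c(length(slices), rows, cols))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$pixels
  origin_z <- if (is.finite(z[1])) z[1] else 0
  ct_volume(arr,
            spacing = c(slice_spacing, slices[[1]]$row_spacing,
                        slices[[1]]$col_spacing),
            origin = c(origin_z, 0, 0))
}

dcm_elem <- function(group, elem, vr, value) {
  h <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
         writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
         charToRaw(vr))
  if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
  if (vr %in% LONG_VRS) {
    c(h, as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(h, writeBin(as.integer(length(value)), raw(), size = 2,
                  endian = "little"), value)
  }
}

dcm_ds_raw <- function(x) charToRaw(paste(sprintf("%.10g", x), collapse = "\\"))
dcm_us_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")

write_dicom_series <- function(volume, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create DICOM series directory: ", path)
  d <- vol_dim(volume)
  intercept <- -1024; slope <- 1
  for (k in seq_len(d[1])) {
    sl <- volume$intensities[k, , ]
    stored <- round((sl - intercept) / slope)
    if (any(stored < -32768 | stored > 32767))
      stop("intensities out of 16-bit DICOM range")
    z <- volume$origin[1] + (k - 1) * volume$spacing[1]
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    body <- c(
      dcm_elem(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
      dcm_elem(0x0008, 0x0060, "CS", charToRaw("CT")),
      dcm_elem(0x0020, 0x0032, "DS", dcm_ds_raw(c(0, 0, z))),
      dcm_elem(0x0020, 0x1041, "DS", dcm_ds_raw(z)),
      dcm_elem(0x0028, 0x0002, "US", dcm_us_raw(1)),
      dcm_elem(0x0028, 0x0010, "US", dcm_us_raw(d[2])),
      dcm_elem(0x0028, 0x0011, "US", dcm_us_raw(d[3])),
      dcm_elem(0x0028, 0x0030, "DS",
               dcm_ds_raw(c(volume$spacing[2], volume$spacing[3]))),
      dcm_elem(0x0028, 0x0100, "US", dcm_us_raw(16)),
      dcm_elem(0x0028, 0x0101, "US", dcm_us_raw(16)),
      dcm_elem(0x0028, 0x0102, "US", dcm_us_raw(15)),
      dcm_elem(0x0028, 0x0103, "US", dcm_us_raw(1)),
      dcm_elem(0x0028, 0x1052, "DS", dcm_ds_raw(intercept)),
      dcm_elem(0x0028, 0x1053, "DS", dcm_ds_raw(slope)),
      dcm_elem(0x7FE0, 0x0010, "OW", px)
    )
    out <- c(raw(128), charToRaw("DICM"), body)
    writeBin(out, file.path(path, sprintf("slice_%04d.dcm", k)))
  }
  invisible(path)
}
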