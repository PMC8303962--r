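#' Read and write volumes in standard formats
#'
#' Supported: NIfTI-1 (`.nii`, `.nii.gz`) via RNifti, MetaImage
#' (`.mhd`/`.mha`, uncompressed), and reading an uncompressed little-endian
#' DICOM series from a directory. Only axis-aligned geometries with positive
#' spacing are supported; anything encoded through a non-diagonal direction
#' matrix raises an explicit unsupported-orientation error rather than being
#' silently misregistered.
#'
#' @param path file path (or directory for a DICOM series).
#' @return `read_volume` returns a [new_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  if (grepl("\\.(mhd|mha)$", lp)) return(read_metaimage(path))
  stop("unknown volume format: ", path,
       " (expected .nii, .nii.gz, .mhd, .mha or a DICOM directory)")
}

#' @rdname read_volume
#' @param volume a [new_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(write_nifti_volume(volume, path))
  if (grepl("\\.(mhd|mha)$", lp)) return(write_metaimage(volume, path))
  stop("unknown volume format for writing: ", path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  R <- m[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-6 || any(diag(R) <= 0))
    stop("unsupported orientation: NIfTI direction matrix is not ",
         "axis-aligned with positive spacing")
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("only 3-D NIfTI volumes are supported")
  new_volume(a, spacing = diag(R), origin = m[1:3, 4])
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- MetaImage (.mhd/.mha), uncompressed ----------------------------------

.met_types <- list(
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupt MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("corrupt MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L) stop("only 3-D MetaImage volumes are supported")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      toupper(hdr$BinaryDataByteOrderMSB) == "TRUE")
    stop("big-endian MetaImage data is not supported")
  tm <- hdr$TransformMatrix
  if (!is.null(tm)) {
    tmv <- as.numeric(strsplit(tm, "\\s+")[[1]])
    if (max(abs(tmv - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-9)
      stop("unsupported orientation: MetaImage TransformMatrix is not identity")
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tinfo <- .met_types[[hdr$ElementType]]
  if (is.null(tinfo)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
    vals <- readBin(raw_con, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    rc <- file(raw_path, "rb")
    on.exit(close(rc), add = TRUE)
    vals <- readBin(rc, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  new_volume(array(as.numeric(vals), dims), spacing, origin)
}

write_metaimage <- function(volume, path) {
  v <- volume$voxels
  is_int <- max(abs(v - round(v))) == 0
  if (is_int && min(v) >= -32768 && max(v) <= 32767) {
    etype <- "MET_SHORT"; size <- 2L; vals <- as.integer(round(v))
  } else {
    etype <- "MET_DOUBLE"; size <- 8L; vals <- as.numeric(v)
  }
  mha <- grepl("\\.mha$", tolower(path))
  data_file <- if (mha) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                               ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(volume$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(volume$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(v), collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", data_file))
  if (mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(vals, con, size = size, endian = "little")
  } else {
    writeLines(hdr, path)
    rc <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rc))
    writeBin(vals, rc, size = size, endian = "little")
  }
  invisible(path)
}

#' Null-coalescing helper
#'
#' @param a,b values; `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, else `b`.
#' @export
#' @name op-null-default
`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- DRR image export ------------------------------------------------------

#' Write a DRR image as PNG preview plus lossless raw grid and JSON sidecar
#'
#' The PNG is an 8-bit min-max scaled preview; exact line-integral values are
#' stored as a single-slice MetaImage next to it, and the sidecar records the
#' scaling, pixel spacing and view tag needed to reconstruct raw values.
#'
#' @param drr a [drr_image()].
#' @param path output PNG path; sidecar and raw grid derive from it.
#' @return Invisibly, the PNG path.
#' @export
write_drr_png <- function(drr, path) {
  stopifnot(inherits(drr, "drr_image"))
  px <- drr$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  # PNG rows run top-to-bottom; detector v axis runs bottom-to-top
  png::writePNG(t(scaled)[rev(seq_len(ncol(px))), , drop = FALSE], path)
  raw_path <- sub("\\.png$", ".mha", path, ignore.case = TRUE)
  vol <- new_volume(array(px, c(dim(px), 1L)),
                    spacing = c(drr$pixel_spacing, 1), origin = c(0, 0, 0))
  write_metaimage(vol, raw_path)
  sidecar <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(list(
    view = drr$view, pixel_spacing_mm = drr$pixel_spacing,
    detector_px = dim(px), raw_min = rng[1], raw_max = rng[2],
    raw_grid = basename(raw_path),
    units = "intensity*mm line integral"), sidecar,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
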