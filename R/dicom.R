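# Minimal DICOM series reader: uncompressed little-endian (explicit or
# implicit VR) single-frame CT slices, axis-aligned orientation. Enough to
# assemble a volume from a directory of slice files; anything fancier
# (compressed transfer syntaxes, oblique orientations, sequences with
# undefined length) is rejected explicitly.

read_uint <- function(raw, little = TRUE) {
  sum(as.integer(raw) * 256^(if (little) seq_along(raw) - 1 else rev(seq_along(raw)) - 1))
}

.dicom_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  tags <- list()
  explicit <- TRUE   # file meta group is always explicit little endian
  explicit_pending <- FALSE
  meta_end <- NA_integer_
  transfer_syntax <- "1.2.840.10008.1.2.1"
  while (pos + 8L <= length(raw) + 1L) {
    if (!is.na(meta_end) && pos > meta_end && explicit_pending) {
      # switch to the dataset transfer syntax after the meta group
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
      explicit_pending <- FALSE
    }
    group <- read_uint(raw[pos:(pos + 1L)])
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    in_meta <- group == 2L
    use_explicit <- if (in_meta) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .dicom_long_vrs) {
        len <- read_uint(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint(raw[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    value <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
    if (key == "0002,0000") {
      meta_end <- pos + read_uint(value)
      explicit_pending <- TRUE
    }
    if (key == "0002,0010")
      transfer_syntax <- trimws(rawToChar(value[value != as.raw(0)]))
    if (key == "7fe0,0010") break
  }
  tags
}

dicom_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value[el$value != as.raw(0)]))
}

dicom_nums <- function(tags, key) {
  s <- dicom_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  read_uint(el$value[1:2])
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    rows <- dicom_uint16(tags, "0028,0010")
    cols <- dicom_uint16(tags, "0028,0011")
    bits <- dicom_uint16(tags, "0028,0100") %||% 16L
    pixrep <- dicom_uint16(tags, "0028,0103") %||% 0L
    if (is.null(rows) || is.null(cols)) stop("DICOM slice lacks Rows/Columns: ", f)
    if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
    iop <- dicom_nums(tags, "0020,0037")
    if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("unsupported orientation: DICOM ImageOrientationPatient is not axis-aligned")
    ipp <- dicom_nums(tags, "0020,0032") %||% c(0, 0, 0)
    ps <- dicom_nums(tags, "0028,0030") %||% c(1, 1)   # (row, col) = (y, x)
    slope <- dicom_nums(tags, "0028,1053") %||% 1
    intercept <- dicom_nums(tags, "0028,1052") %||% 0
    pd <- tags[["7fe0,0010"]]
    if (is.null(pd)) stop("DICOM slice lacks PixelData: ", f)
    con <- rawConnection(pd$value)
    on.exit(close(con))
    v <- readBin(con, "integer", n = rows * cols, size = 2L,
                 signed = pixrep == 1L, endian = "little")
    # PixelData is row-major: index = row * cols + col -> matrix[col, row]
    m <- matrix(as.numeric(v) * slope + intercept, nrow = cols, ncol = rows)
    list(pixels = m, ipp = ipp, ps = ps)
  })
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  d1 <- dim(slices[[1]]$pixels)
  if (!all(vapply(slices, function(s) identical(dim(s$pixels), d1), logical(1))))
    stop("DICOM slices have inconsistent dimensions")
  dz <- if (length(z) > 1) diff(z) else 1
  if (length(z) > 1 && (any(dz <= 0) || max(dz) - min(dz) > 1e-4))
    stop("DICOM slice positions are not uniformly spaced")
  arr <- array(0, c(d1, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  ps <- slices[[1]]$ps
  new_volume(arr,
             spacing = c(ps[2], ps[1], if (length(z) > 1) dz[1] else 1),
             origin = c(slices[[1]]$ipp[1:2], z[1]))
}
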