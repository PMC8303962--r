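test_that("NIfTI write/read round-trips voxels, spacing and origin", {
  set.seed(5)
  v <- new_volume(array(sample(-1000:2000, 8^3, TRUE), c(8, 8, 8)),
                  spacing = c(0.5, 0.5, 5), origin = c(-10, 3, 7))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
})

test_that("MetaImage round-trips exactly, in both single and header+raw form", {
  set.seed(6)
  vi <- new_volume(array(sample(-1000:2000, 4 * 5 * 6, TRUE), c(4, 5, 6)),
                   spacing = c(0.5, 0.5, 5.0), origin = c(1, -2, 3))
  vf <- new_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                   spacing = c(0.5, 0.5, 5.0), origin = c(0, 0, 0))
  for (ext in c(".mha", ".mhd")) {
    fi <- tempfile(fileext = ext)
    write_volume(vi, fi)
    got <- read_volume(fi)
    expect_identical(got$voxels, vi$voxels)   # integer HU: bit-exact
    expect_identical(got$spacing, vi$spacing) # (0.5, 0.5, 5) preserved exactly
  }
  ff <- tempfile(fileext = ".mha")
  write_volume(vf, ff)
  expect_lt(max(abs(read_volume(ff)$voxels - vf$voxels)), 1e-6)
})

test_that("a synthetic DICOM series assembles into the right volume", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  td <- tempfile(); dir.create(file.path(td, "dcm"), recursive = TRUE)
  py <- c(
    "import numpy as np",
    "from pydicom.dataset import Dataset, FileDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, generate_uid",
    "rng = np.random.default_rng(7)",
    "arr = rng.integers(-1000, 2000, size=(3, 5, 4))",
    "for k in range(3):",
    "    ds = FileDataset(None, Dataset(), file_meta=Dataset(), preamble=b'\\0'*128)",
    "    ds.file_meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.2'",
    "    ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()",
    "    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "    ds.Rows, ds.Columns = 5, 4",
    "    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "    ds.PixelRepresentation = 1; ds.SamplesPerPixel = 1",
    "    ds.PhotometricInterpretation = 'MONOCHROME2'",
    "    ds.RescaleSlope = '1'; ds.RescaleIntercept = '0'",
    "    ds.PixelSpacing = ['0.7', '0.9']",
    "    ds.ImagePositionPatient = ['5', '-3', str(10 + 2.5*k)]",
    "    ds.ImageOrientationPatient = ['1','0','0','0','1','0']",
    "    ds.PixelData = arr[k].astype(np.int16).tobytes()",
    sprintf("    ds.save_as(r'%s/dcm/s%%d.dcm' %% k, enforce_file_format=True)",
            td),
    sprintf("np.savetxt(r'%s/arr.txt', arr.flatten(), fmt='%%d')", td))
  pyf <- file.path(td, "mk.py")
  writeLines(py, pyf)
  status <- system2("python", pyf, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(td, "arr.txt")),
              info = paste(status, collapse = "\n"))
  vd <- read_volume(file.path(td, "dcm"))
  expect_equal(dim(vd$voxels), c(4L, 5L, 3L))        # depth 3 from 3 slices
  expect_equal(vd$spacing, c(0.9, 0.7, 2.5))          # slice spacing from IPP
  expect_equal(vd$origin, c(5, -3, 10))
  ref <- scan(file.path(td, "arr.txt"), quiet = TRUE) # C-order: col fastest
  expect_identical(vd$voxels, array(as.numeric(ref), c(4, 5, 3)))
})

test_that("unknown formats and oblique orientations are rejected loudly", {
  expect_error(read_volume("nope.xyz"), "unknown volume format")
  v <- new_volume(array(0, c(3, 3, 3)))
  expect_error(write_volume(v, "nope.xyz"), "unknown volume format")
  # a MetaImage with a rotated direction matrix must not be read silently
  f <- tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               "TransformMatrix = 0 1 0 -1 0 0 0 0 1",
               "Offset = 0 0 0", "ElementSpacing = 1 1 1",
               "DimSize = 2 2 2", "ElementType = MET_SHORT",
               "ElementDataFile = LOCAL"), f)
  con <- file(f, "ab")
  writeBin(integer(8), con, size = 2L, endian = "little")
  close(con)
  expect_error(read_volume(f), "unsupported orientation")
})

test_that("volume validation enforces the data model", {
  expect_error(new_volume(matrix(0, 2, 2)), "3-D")
  expect_error(new_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(new_volume(array(NA_real_, c(2, 2, 2))), "finite")
})

test_that("DRR export writes PNG preview, lossless raw grid and sidecar", {
  d <- drr_image(matrix(runif(64), 8, 8), pixel_spacing = c(2, 2), view = "ap")
  f <- tempfile(fileext = ".png")
  write_drr_png(d, f)
  expect_true(file.exists(f))
  raw <- read_volume(sub("\\.png$", ".mha", f))
  expect_equal(array(raw$voxels, dim(d$pixels)), unclass(d$pixels),
               ignore_attr = TRUE)
  sc <- jsonlite::read_json(sub("\\.png$", ".json", f), simplifyVector = TRUE)
  expect_equal(sc$raw_min, min(d$pixels))
  expect_equal(sc$pixel_spacing_mm, c(2, 2))
})
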