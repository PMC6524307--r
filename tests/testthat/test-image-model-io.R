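test_that("ct_image validates its invariants", {
  expect_error(ct_image(matrix(NA_real_, 2, 2)), "finite")
  expect_error(ct_image(matrix(0, 2, 2), spacing = c(0, 1)), "positive")
  img <- ct_image(matrix(0, 4, 4), spacing = c(0.76, 0.76),
                  modality = "MVCT")
  expect_s3_class(img, "ct_image")
  expect_identical(dim(img$pixels), c(4L, 4L))
})

test_that("ct_series rejects mismatched or unordered slices", {
  a <- ct_image(matrix(0, 4, 4), slice_index = 1)
  b <- ct_image(matrix(0, 4, 4), slice_index = 2)
  c_bad <- ct_image(matrix(0, 5, 4), slice_index = 3)
  expect_s3_class(ct_series(list(a, b)), "ct_series")
  expect_error(ct_series(list(a, b, c_bad)), "same shape")
  expect_error(ct_series(list(b, a)), "increasing")
})

test_that("windowing maps HU linearly with clipping at the edges", {
  w <- windowing(400, 40)
  expect_equal(apply_window(40, w), 127.5)       # window midpoint
  expect_equal(apply_window(240, w), 255)        # upper edge
  expect_equal(apply_window(1500, w), 255)
  expect_equal(apply_window(-160, w), 0)
  expect_equal(apply_window(-60, w), 63.75)      # 255*(-60 + 160)/400
  hu <- seq(-500, 500, by = 7)
  expect_true(all(diff(apply_window(hu, w)) >= 0))   # monotone
  inside <- hu[hu > -160 & hu < 240]
  expect_lt(max(abs(unwindow(apply_window(inside, w), w) - inside)), 1e-9)
  expect_error(windowing(0, 40), "width")
})

test_that("RAW fixture write/read round trip is exact", {
  set.seed(11)
  sl <- lapply(1:3, function(i)
    ct_image(matrix(round(stats::rnorm(64 * 64, 0, 100), 2), 64),
             spacing = c(0.5, 0.5), modality = "MVCT", slice_index = i))
  series <- ct_series(sl, reconstruction_interval = 2)
  base <- file.path(withr::local_tempdir(), "fix")
  write_series(series, base, "RAW")
  # values survive the float32 payload: read twice for bit identity
  back1 <- read_series(base, "RAW")
  write_series(back1, paste0(base, "2"), "RAW")
  back2 <- read_series(paste0(base, "2"), "RAW")
  expect_identical(back1$slices[[2]]$pixels, back2$slices[[2]]$pixels)
  expect_lt(max(abs(back1$slices[[2]]$pixels - series$slices[[2]]$pixels)),
            1e-4)
  expect_equal(back1$slices[[1]]$spacing, c(0.5, 0.5))
  expect_equal(back1$slices[[1]]$modality, "MVCT")
})

test_that("RAW fixture of a zero image reads back as one zero slice", {
  base <- file.path(withr::local_tempdir(), "zero")
  write_series(ct_series(list(ct_image(matrix(0, 64, 64)))), base, "RAW")
  s <- read_series(base)
  expect_length(s$slices, 1)
  expect_true(all(s$slices[[1]]$pixels == 0))
})

test_that("NIfTI round trip preserves HU and spacing", {
  set.seed(3)
  sl <- lapply(1:2, function(i)
    ct_image(matrix(stats::rnorm(32 * 32, 0, 50), 32),
             spacing = c(0.8, 0.8), slice_index = i))
  series <- ct_series(sl, reconstruction_interval = 2)
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_series(series, path, "NIfTI")
  back <- read_series(path)
  expect_equal(back$slices[[1]]$pixels, series$slices[[1]]$pixels,
               tolerance = 1e-6)
  expect_equal(back$slices[[1]]$spacing, c(0.8, 0.8), tolerance = 1e-6)
  expect_equal(back$reconstruction_interval, 2, tolerance = 1e-6)
})

test_that("DICOM round trip recovers HU via rescale slope/intercept", {
  img <- ct_image(matrix(round(seq(-1000, 1200, length.out = 256)), 16),
                  spacing = c(0.76, 0.76), modality = "MVCT")
  dir <- file.path(withr::local_tempdir(), "dcm")
  write_series(ct_series(list(img)), dir, "DICOM")
  back <- read_series(dir, "DICOM")
  expect_equal(back$slices[[1]]$pixels, img$pixels)
  expect_equal(back$slices[[1]]$spacing, c(0.76, 0.76))
})

test_that("DICOM slices are ordered by z position with instance ties", {
  sl <- lapply(1:4, function(i)
    ct_image(matrix(i * 10, 8, 8), slice_index = i))
  dir <- file.path(withr::local_tempdir(), "dcmser")
  write_series(ct_series(sl, reconstruction_interval = 2.5), dir, "DICOM")
  # shuffle file names so ordering must come from the headers
  files <- list.files(dir, full.names = TRUE)
  shuffled <- file.path(dir, sprintf("z%02d.dcm", rev(seq_along(files))))
  file.rename(files, shuffled)
  back <- read_series(dir, "DICOM")
  expect_equal(vapply(back$slices, function(s) s$pixels[1, 1], 1),
               c(10, 20, 30, 40))
  expect_equal(back$reconstruction_interval, 2.5)
})

test_that("an externally written DICOM file reads to the expected HU", {
  # pydicom writes the fixture; stored value 1024 with slope 1 and
  # intercept -1024 must decode to 0 HU
  dir <- withr::local_tempdir()
  script <- file.path(dir, "gen.py")
  writeLines(c(
    "import sys, numpy as np, pydicom",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.2'",
    "meta.MediaStorageSOPInstanceUID = '1.2.3.4.5'",
    "meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "ds = Dataset(); ds.file_meta = meta",
    "ds.Modality = 'CT'; ds.InstanceNumber = 1",
    "ds.ImagePositionPatient = [0, 0, 0]",
    "ds.SamplesPerPixel = 1",
    "ds.PhotometricInterpretation = 'MONOCHROME2'",
    "ds.Rows = 16; ds.Columns = 16",
    "ds.PixelSpacing = [0.5, 0.5]",
    "ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "ds.PixelRepresentation = 1",
    "ds.RescaleIntercept = -1024; ds.RescaleSlope = 1",
    "arr = np.full((16, 16), 1024, dtype=np.int16)",
    "arr[0, 1] = 0",
    "ds.PixelData = arr.tobytes()",
    "pydicom.dcmwrite(sys.argv[1], ds, write_like_original=False)"),
    script)
  dcmdir <- file.path(dir, "d"); dir.create(dcmdir)
  status <- suppressWarnings(system2(
    "python", c(script, file.path(dcmdir, "a.dcm")),
    stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  s <- read_series(dcmdir, "DICOM")
  expect_equal(s$slices[[1]]$pixels[1, 1], 0)       # 1*1024 - 1024
  expect_equal(s$slices[[1]]$pixels[1, 2], -1024)   # 1*0 - 1024
})
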