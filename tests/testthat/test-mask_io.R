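test_that("NIfTI round-trip preserves labels and spacing exactly", {
  ph <- makePhantom(phantomParams(spacing = c(0.8, 0.8, 0.8), seed = 7L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabeledVolume(ph$volume, f)
  back <- readLabeledVolume(f)
  expect_identical(maskArray(back), maskArray(ph$volume))
  expect_equal(voxelSpacing(back), voxelSpacing(ph$volume))

  # anisotropic spacing survives too
  v <- tinyTwoCompartment(spacing = c(0.5, 0.7, 1.1))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabeledVolume(v, f2)
  back2 <- readLabeledVolume(f2)
  expect_identical(maskArray(back2), maskArray(v))
  expect_equal(voxelSpacing(back2), c(0.5, 0.7, 1.1))
})

test_that("an all-zero volume reads as an empty tumour", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabeledVolume(LabeledVolume(array(0L, c(10, 10, 10))), f)
  v <- readLabeledVolume(f)
  expect_true(all(maskArray(v) == 0L))
  expect_identical(dim(maskArray(v)), c(10L, 10L, 10L))
})

test_that("unknown labels and missing files are errors", {
  a <- array(0L, c(6, 6, 6)); a[3, 3, 3] <- 3L
  img <- RNifti::asNifti(a)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(readLabeledVolume(f), "unknown label")
  expect_error(readLabeledVolume(file.path(tempdir(), "nope.nii.gz")),
               "not found")
  # but a label map can rescue a foreign encoding
  v <- readLabeledVolume(f, labelMap = c("3" = 2))
  expect_identical(sum(maskArray(v) == 2L), 1L)
})

test_that("reading reorients a non-canonical volume to the canonical frame", {
  a <- array(0L, c(7, 9, 5)); a[2, 3, 4] <- 1L
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 1)
  m <- diag(c(1, 1, 1, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::orientation(img) <- "LPI"  # flip all three axes
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- readLabeledVolume(f)
  # canonicalization is idempotent: same voxel back in the RAS frame
  expect_identical(which(maskArray(v) == 1L, arr.ind = TRUE)[1, ],
                   c(dim1 = 2L, dim2 = 3L, dim3 = 4L))
})

test_that("manifest parsing groups, sorts and converts dates to months", {
  dir <- withr::local_tempdir()
  v <- tinyTwoCompartment()
  for (i in 1:3) writeLabeledVolume(v, file.path(dir, sprintf("s%d.nii.gz", i)))
  rows <- data.frame(
    patient_id = "P1",
    date = c("2011-01-01", "2012-01-01", "2013-01-01"),
    status = "preoperative",
    mask_path = sprintf("s%d.nii.gz", 1:3))
  mf <- file.path(dir, "manifest.csv")
  write.csv(rows, mf, row.names = FALSE)
  tls <- readTimelineManifest(mf)
  expect_length(tls, 1L)
  s <- sessionTable(tls$P1)
  expected <- as.numeric(as.Date(rows$date) - as.Date(rows$date[1])) / 30.44
  expect_equal(s$months_since_index, expected)
  expect_equal(round(expected, 1), c(0, 12.0, 24.0))

  # JSON dialect gives the same result
  mj <- file.path(dir, "manifest.json")
  jsonlite::write_json(rows, mj, dataframe = "rows")
  tlsJ <- readTimelineManifest(mj)
  expect_equal(sessionTable(tlsJ$P1), s)
})

test_that("manifest parsing is order-invariant and handles many patients", {
  dir <- withr::local_tempdir()
  v <- tinyTwoCompartment()
  writeLabeledVolume(v, file.path(dir, "m.nii.gz"))
  rows <- data.frame(
    patient_id = c("P2", "P1", "P2", "P1"),
    date = c("2021-05-01", "2020-01-01", "2020-03-15", "2021-01-01"),
    status = "preoperative",
    mask_path = "m.nii.gz")
  mf <- file.path(dir, "a.csv"); write.csv(rows, mf, row.names = FALSE)
  tls <- readTimelineManifest(mf)
  expect_named(tls, c("P1", "P2"))
  expect_false(is.unsorted(sessionTable(tls$P1)$session_date, strictly = TRUE))
  expect_false(is.unsorted(sessionTable(tls$P2)$session_date, strictly = TRUE))

  shuf <- rows[c(3, 1, 4, 2), ]
  mf2 <- file.path(dir, "b.csv"); write.csv(shuf, mf2, row.names = FALSE)
  tls2 <- readTimelineManifest(mf2)
  expect_equal(lapply(tls2, sessionTable), lapply(tls, sessionTable))
})

test_that("single-session timelines are valid; bad rows are handled per rule", {
  dir <- withr::local_tempdir()
  v <- tinyTwoCompartment()
  writeLabeledVolume(v, file.path(dir, "m.nii.gz"))
  one <- data.frame(patient_id = "P1", date = "2020-01-01",
                    status = "preoperative", mask_path = "m.nii.gz")
  mf <- file.path(dir, "one.csv"); write.csv(one, mf, row.names = FALSE)
  tls <- readTimelineManifest(mf)
  expect_identical(nrow(sessionTable(tls$P1)), 1L)

  # a missing mask on a follow-up row: dropped with a warning
  rows <- data.frame(patient_id = "P1",
                     date = c("2020-01-01", "2021-01-01"),
                     status = "preoperative",
                     mask_path = c("m.nii.gz", "gone.nii.gz"))
  mf2 <- file.path(dir, "drop.csv"); write.csv(rows, mf2, row.names = FALSE)
  expect_warning(tls2 <- readTimelineManifest(mf2), "missing mask")
  expect_identical(nrow(sessionTable(tls2$P1)), 1L)

  # the same failure on the index row rejects the manifest
  rows$mask_path <- rev(rows$mask_path)
  mf3 <- file.path(dir, "rej.csv"); write.csv(rows, mf3, row.names = FALSE)
  expect_error(readTimelineManifest(mf3), "index session invalid")

  # duplicate (patient, date) rows are flagged
  dup <- data.frame(patient_id = "P1",
                    date = c("2020-01-01", "2020-01-01"),
                    status = "preoperative", mask_path = "m.nii.gz")
  mf4 <- file.path(dir, "dup.csv"); write.csv(dup, mf4, row.names = FALSE)
  expect_warning(readTimelineManifest(mf4), "duplicate")
})
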