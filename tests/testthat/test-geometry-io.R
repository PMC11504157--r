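test_that("DICOM write/read round trip preserves geometry and pixels", {
  set.seed(10)
  g <- seriesGeometry(1.25, 1.5, 5.5, 6, 24, 30, "axial")
  sl <- lapply(1:3, function(i) matrix(sample(0:4095, 24 * 30, TRUE), 24, 30))
  st <- sliceStack(sl, g, "rtA", slicePositions = c(0, 5.5, 11))
  d <- file.path(tempdir(), "rt-series")
  man <- writeDicomSeries(st, d)
  expect_equal(nrow(man), 3)
  st2 <- readDicomSeries(d)
  expect_identical(unclass(geometry(st2)), unclass(g))
  expect_equal(subjectId(st2), "rtA")
  expect_equal(st2@slicePositions, c(0, 5.5, 11))
  for (i in 1:3) expect_true(all(slices(st2)[[i]] == sl[[i]]))

  # absent SpacingBetweenSlices stays absent; coronal orientation survives
  g2 <- seriesGeometry(2, 2, 4, NA, 8, 8, "coronal")
  st3 <- sliceStack(list(matrix(5, 8, 8)), g2, "rtB")
  d2 <- file.path(tempdir(), "rt-coronal")
  suppressMessages(writeDicomSeries(st3, d2))
  st4 <- suppressMessages(readDicomSeries(d2))
  expect_true(is.na(spacingBetweenSlices(geometry(st4))))
  expect_equal(orientation(geometry(st4)), "coronal")
  expect_equal(length(st4), 1L)
})

test_that("slices come back sorted by position regardless of file order", {
  g <- seriesGeometry(1, 1, 5, 5, 8, 8, "axial")
  sl <- lapply(1:4, function(i) matrix(i, 8, 8))
  st <- sliceStack(sl, g, "sortA", slicePositions = c(0, 5, 10, 15))
  d <- file.path(tempdir(), "sort-series")
  writeDicomSeries(st, d)
  # shuffle file names so directory order disagrees with position
  f <- list.files(d, full.names = TRUE)
  file.rename(f[1], file.path(d, "ZZZZ.dcm"))
  st2 <- readDicomSeries(d)
  expect_equal(vapply(slices(st2), function(m) m[1, 1], numeric(1)), 1:4)
})

test_that("reader rejects empty, mixed and incomplete input", {
  d <- file.path(tempdir(), "empty-series")
  dir.create(d, showWarnings = FALSE)
  expect_error(readDicomSeries(d), "input error")

  # two different series in one directory
  g <- seriesGeometry(1, 1, 5, 5, 8, 8, "axial")
  stA <- sliceStack(list(matrix(0, 8, 8)), g, "mixA")
  stB <- sliceStack(list(matrix(0, 8, 8)), g, "mixB")
  dm <- file.path(tempdir(), "mixed-series")
  writeDicomSeries(stA, dm)
  file.rename(file.path(dm, "IMG0001.dcm"), file.path(dm, "A.dcm"))
  writeDicomSeries(stB, dm)
  expect_error(readDicomSeries(dm), "ambiguity")

  # missing PixelSpacing is named in the error
  dp <- file.path(tempdir(), "no-ps")
  dir.create(dp, showWarnings = FALSE)
  body <- c(tkvseg:::.dcmElement(0x0018, 0x0050, "DS", "5"),
            tkvseg:::.dcmElement(0x0028, 0x0010, "US", 4L),
            tkvseg:::.dcmElement(0x0028, 0x0011, "US", 4L))
  con <- file(file.path(dp, "x.dcm"), "wb")
  writeBin(raw(128), con); writeBin(charToRaw("DICM"), con)
  writeBin(body, con); close(con)
  expect_error(readDicomSeries(dp), "PixelSpacing")
})

test_that("prepareForModel resizes, normalises and records the native grid", {
  expect_equal(unname(prepareForModel(matrix(255, 256, 256))[1, 1]), 1)
  expect_true(all(prepareForModel(matrix(255, 256, 256)) == 1))
  z <- prepareForModel(matrix(0, 100, 37))
  expect_equal(dim(z), c(256L, 256L))
  expect_true(all(z == 0))
  expect_equal(attr(z, "nativeDim"), c(100L, 37L))
  expect_error(prepareForModel(1:10), "shape error")

  # against the independently coded bilinear oracle
  set.seed(3)
  chk <- matrix(rep(c(0, 245), length.out = 24 * 24), 24, 24) +
    matrix(runif(24 * 24, 0, 10), 24, 24)
  got <- prepareForModel(chk, size = 40L)
  ref <- oracleBilinearResize(chk, 40, 40) / 255
  expect_lt(max(abs(got - ref)), 1e-6)

  # output always lies in [0, 1] whatever the input intensities
  big <- matrix(runif(50 * 70, 0, 4095), 50, 70)
  out <- prepareForModel(big, size = 64L)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(dim(out), c(64L, 64L))
})

test_that("restoreToGrid maps masks back to the native grid", {
  g <- seriesGeometry(1, 1, 5, 5, 64, 64, "axial")
  expect_true(all(restoreToGrid(matrix(1, 256, 256), g) == 1))
  expect_true(all(restoreToGrid(matrix(0, 256, 256), g) == 0))
  expect_error(restoreToGrid(matrix(0.5, 256, 256), g), "domain error")

  # identity when model and native grids coincide
  set.seed(4)
  m <- randomMask(256, 256, 0.3)
  g256 <- seriesGeometry(1, 1, 5, 5, 256, 256, "axial")
  expect_identical(restoreToGrid(m, g256), m)

  # area scaling: centered disk upsampled 2x quadruples the pixel count
  xy <- expand.grid(r = 1:256, c = 1:256)
  disk <- matrix(as.numeric((xy$r - 128.5)^2 + (xy$c - 128.5)^2 <= 60^2),
                 256, 256)
  g512 <- seriesGeometry(1, 1, 5, 5, 512, 512, "axial")
  up <- restoreToGrid(disk, g512)
  expect_lt(abs(sum(up) - 4 * sum(disk)) / (4 * sum(disk)), 0.02)
})

test_that("written series parse with an independent DICOM reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(11)
  g <- seriesGeometry(1.75, 2.25, 6.5, 7, 16, 20, "axial")
  sl <- list(matrix(sample(0:255, 16 * 20, TRUE), 16, 20))
  st <- sliceStack(sl, g, "oracleA", slicePositions = 12.5)
  d <- file.path(tempdir(), "pydicom-series")
  writeDicomSeries(st, d)
  f <- list.files(d, full.names = TRUE)[1]
  code <- paste0(
    "import pydicom; ds = pydicom.dcmread('", f, "'); ",
    "print(float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]), ",
    "float(ds.SliceThickness), float(ds.SpacingBetweenSlices), ",
    "int(ds.Rows), int(ds.Columns), int(ds.pixel_array.sum()))")
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals, c(1.75, 2.25, 6.5, 7, 16, 20, sum(sl[[1]])))
})
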