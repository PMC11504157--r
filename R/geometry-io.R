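# DICOM series I/O and model-grid resampling.

.orientationIOP <- function(orientation) {
  # direction cosines of image rows/columns in patient coordinates
  switch(orientation,
    axial   = c(1, 0, 0, 0, 1, 0),
    coronal = c(1, 0, 0, 0, 0, -1),
    stop("unsupported orientation: ", orientation))
}

.iopNormal <- function(iop) {
  r <- iop[1:3]; c3 <- iop[4:6]
  c(r[2] * c3[3] - r[3] * c3[2],
    r[3] * c3[1] - r[1] * c3[3],
    r[1] * c3[2] - r[2] * c3[1])
}

.orientationFromIOP <- function(iop) {
  n <- abs(.iopNormal(iop))
  ax <- which.max(n)
  if (ax == 3) "axial"
  else if (ax == 2) "coronal"
  else stop("unsupported orientation (sagittal-like normal)")
}

#' Read a DICOM series from a directory
#'
#' Parses every \code{.dcm} file in \code{directoryPath}, checks that they
#' belong to a single series, extracts the geometric metadata
#' (PixelSpacing, SliceThickness, SpacingBetweenSlices, Rows, Columns,
#' orientation) and returns the slices sorted by position along the slice
#' normal (falling back to InstanceNumber when positions are absent).
#' RescaleSlope/RescaleIntercept, when present, are applied to the stored
#' pixel values. Absent optional tags are reported with
#' \code{message()} and recorded as \code{NA}, never silently defaulted.
#'
#' @param directoryPath directory containing the \code{.dcm} files of one
#'   series.
#' @return A \linkS4class{SliceStack}.
#' @seealso [writeDicomSeries()] for the inverse operation.
#' @export
readDicomSeries <- function(directoryPath) {
  if (!dir.exists(directoryPath))
    stop("input error: directory does not exist: ", directoryPath)
  files <- list.files(directoryPath, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    stop("input error: no DICOM (.dcm) files in ", directoryPath)
  parsed <- lapply(files, .readDicomFile)

  uids <- vapply(parsed, function(e) {
    u <- .strValue(e, "0020,000E"); if (is.null(u)) "" else u
  }, character(1))
  if (length(unique(uids)) > 1)
    stop("ambiguity error: directory mixes multiple series (SeriesInstanceUID)")

  e1 <- parsed[[1]]
  ps <- .dsValues(e1, "0028,0030")
  if (is.null(ps)) stop("metadata error: missing tag PixelSpacing (0028,0030)")
  st <- .dsValues(e1, "0018,0050")
  if (is.null(st)) stop("metadata error: missing tag SliceThickness (0018,0050)")
  rows <- .usValue(e1, "0028,0010")
  if (is.null(rows)) stop("metadata error: missing tag Rows (0028,0010)")
  cols <- .usValue(e1, "0028,0011")
  if (is.null(cols)) stop("metadata error: missing tag Columns (0028,0011)")
  sbs <- .dsValues(e1, "0018,0088")
  if (is.null(sbs)) {
    message("SpacingBetweenSlices (0018,0088) absent; recorded as NA")
    sbs <- NA_real_
  }
  iop <- .dsValues(e1, "0020,0037")
  if (is.null(iop)) {
    message("ImageOrientationPatient (0020,0037) absent; assuming axial")
    orient <- "axial"
    iop <- .orientationIOP("axial")
  } else orient <- .orientationFromIOP(iop)
  normal <- .iopNormal(iop)

  pos <- vapply(parsed, function(e) {
    p <- .dsValues(e, "0020,0032")
    if (is.null(p)) NA_real_ else sum(p * normal)
  }, numeric(1))
  inst <- vapply(parsed, function(e) {
    v <- .strValue(e, "0020,0013")
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  ord <- if (!anyNA(pos)) order(pos, inst, na.last = TRUE) else {
    message("ImagePositionPatient absent on some slices; ordering by InstanceNumber")
    order(inst, na.last = TRUE)
  }
  parsed <- parsed[ord]; pos <- pos[ord]

  slicesList <- lapply(parsed, function(e) {
    r <- .usValue(e, "0028,0010"); cl <- .usValue(e, "0028,0011")
    if (r != rows || cl != cols)
      stop("metadata error: inconsistent Rows/Columns within series")
    pd <- e[["7FE0,0010"]]
    if (is.null(pd)) stop("metadata error: missing tag PixelData (7FE0,0010)")
    v <- readBin(pd$value, integer(), n = r * cl, size = 2, signed = FALSE,
                 endian = "little")
    m <- matrix(v, nrow = r, byrow = TRUE)
    slope <- .dsValues(e, "0028,1053"); icpt <- .dsValues(e, "0028,1052")
    if (!is.null(slope) || !is.null(icpt)) {
      message("applying RescaleSlope/RescaleIntercept to stored values")
      m <- m * (if (is.null(slope)) 1 else slope) +
        (if (is.null(icpt)) 0 else icpt)
    }
    m
  })

  subj <- .strValue(e1, "0010,0020")
  if (is.null(subj)) subj <- "unknown"
  geom <- seriesGeometry(ps[1], ps[2], st[1], sbs[1], rows, cols, orient)
  sliceStack(slicesList, geom, subjectId = subj, slicePositions = pos)
}

#' Write a SliceStack as a DICOM series
#'
#' Emits one single-frame DICOM file per slice (Explicit VR Little
#' Endian) carrying PixelSpacing, SliceThickness, SpacingBetweenSlices
#' (only when present in the geometry), Rows, Columns, orientation and
#' position tags, such that \code{readDicomSeries(writeDicomSeries(s))}
#' restores the geometry exactly and the pixel data elementwise.
#'
#' @param stack a \linkS4class{SliceStack}.
#' @param directoryPath output directory (created if needed).
#' @return Invisibly, a data.frame manifest with columns \code{file},
#'   \code{instanceNumber}, \code{position}.
#' @export
writeDicomSeries <- function(stack, directoryPath) {
  if (!is(stack, "SliceStack")) stop("input error: 'stack' must be a SliceStack")
  validObject(stack)
  if (length(stack@slices) == 0) stop("input error: stack has zero slices")
  ok <- dir.create(directoryPath, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directoryPath))
    stop("I/O error: cannot create directory ", directoryPath)
  g <- stack@geometry
  iop <- .orientationIOP(g@orientation)
  n <- length(stack@slices)
  pos <- stack@slicePositions
  if (anyNA(pos)) {
    step <- if (!is.na(g@spacingBetweenSlices)) g@spacingBetweenSlices else
      g@sliceThickness
    pos <- (seq_len(n) - 1) * step
  }
  seriesUID <- .makeUID(paste0(stack@subjectId, ":series"))
  studyUID <- .makeUID(paste0(stack@subjectId, ":study"))
  files <- character(n)
  for (i in seq_len(n)) {
    ipp <- switch(g@orientation,
      axial = c(0, 0, pos[i]),
      coronal = c(0, pos[i], 0))
    f <- file.path(directoryPath, sprintf("IMG%04d.dcm", i))
    .writeDicomFile(f, stack@slices[[i]], g, stack@subjectId, seriesUID,
                    studyUID, i, ipp, iop,
                    sopInstanceUID = .makeUID(paste0(stack@subjectId, ":", i)))
    files[i] <- f
  }
  invisible(data.frame(file = files, instanceNumber = seq_len(n),
                       position = pos))
}

#' Resample a slice to the model grid
#'
#' Bilinearly resamples a grayscale slice to \code{size x size} (256 by
#' default) and rescales intensities to \code{[0, 1]} by division by 255
#' (clipped). Non-square slices are resized anisotropically (no
#' letterboxing), so the inverse map back to the native grid is a plain
#' resize; the native dimensions are recorded in the
#' \code{"nativeDim"} attribute.
#'
#' @param slice a 2D numeric matrix of non-negative intensities.
#' @param size output side length in pixels (default 256).
#' @return a \code{size x size} matrix with values in \code{[0, 1]}.
#' @export
prepareForModel <- function(slice, size = 256L) {
  if (!is.matrix(slice) || any(dim(slice) < 1))
    stop("shape error: 'slice' must be a 2D matrix with positive dimensions")
  out <- .bilinearResample(slice, size, size) / 255
  out <- pmin(pmax(out, 0), 1)
  attr(out, "nativeDim") <- dim(slice)
  out
}

#' Map a model-grid binary mask back to the native pixel grid
#'
#' Nearest-neighbour resampling of a binary mask from the model grid to
#' the series' native \code{(nRows, nCols)} grid, on which pixel areas
#' are physically meaningful via PixelSpacing.
#'
#' @param mask a binary matrix (values 0/1).
#' @param geom a \linkS4class{SeriesGeometry} giving the target grid.
#' @return a binary \code{nRows x nCols} matrix.
#' @export
restoreToGrid <- function(mask, geom) {
  if (!is.matrix(mask)) stop("domain error: 'mask' must be a matrix")
  if (!all(mask %in% c(0, 1)))
    stop("domain error: 'mask' must be binary (0/1)")
  .nearestResample(mask, geom@nRows, geom@nCols)
}
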