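# Minimal DICOM codec: Explicit VR Little Endian, single-frame grayscale.
# Covers the tag set the volumetry pipeline depends on (PixelSpacing,
# SliceThickness, SpacingBetweenSlices, Rows, Columns, position and
# orientation tags) plus enough bookkeeping (UIDs, transfer syntax) that
# standard readers accept the files. Compressed transfer syntaxes and
# multi-frame objects are out of scope.

.DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_ROOT <- "1.2.826.0.1.3680043.8.498"  # generic test-UID root

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.uint32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.padEven <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.fmtDS <- function(x) {
  # DS values are limited to 16 bytes
  vapply(x, function(v) {
    s <- formatC(v, format = "g", digits = 10)
    gsub(" ", "", s)
  }, character(1))
}

# Encode one data element, explicit VR little endian
.dcmElement <- function(group, element, vr, value) {
  if (vr %in% c("UI")) {
    v <- .padEven(charToRaw(value), pad = as.raw(0x00))
  } else if (vr %in% c("CS", "LO", "PN", "SH", "DS", "IS")) {
    v <- .padEven(charToRaw(value))
  } else if (vr == "US") {
    v <- .uint16le(value)
  } else if (vr == "UL") {
    v <- .uint32le(value)
  } else if (vr %in% c("OB", "OW")) {
    v <- value  # already raw
  } else {
    stop("unsupported VR in writer: ", vr)
  }
  head <- c(.uint16le(group), .uint16le(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0, 0)), .uint32le(length(v)), v)
  } else {
    if (length(v) > 65535L) stop("element too long for short VR")
    c(head, .uint16le(length(v)), v)
  }
}

# Deterministic pseudo-UID from a string key
.makeUID <- function(key) {
  codes <- utf8ToInt(key)
  h1 <- sum(codes * seq_along(codes)) %% 999999937
  h2 <- sum(codes * rev(seq_along(codes))) %% 999999893
  paste(.UID_ROOT, h1, h2, sep = ".")
}

# Write one slice as a DICOM file. pixels: integer matrix (row-major image
# rows = matrix rows), values 0..65535.
.writeDicomFile <- function(path, pixels, geom, subjectId, seriesUID, studyUID,
                            instanceNumber, imagePosition, imageOrientation,
                            sopInstanceUID) {
  stopifnot(is.matrix(pixels))
  body <- c(
    .dcmElement(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    .dcmElement(0x0008, 0x0018, "UI", sopInstanceUID),
    .dcmElement(0x0008, 0x0060, "CS", "MR"),
    .dcmElement(0x0010, 0x0010, "PN", subjectId),
    .dcmElement(0x0010, 0x0020, "LO", subjectId),
    .dcmElement(0x0018, 0x0050, "DS", .fmtDS(geom@sliceThickness))
  )
  if (!is.na(geom@spacingBetweenSlices))
    body <- c(body, .dcmElement(0x0018, 0x0088, "DS",
                                .fmtDS(geom@spacingBetweenSlices)))
  body <- c(body,
    .dcmElement(0x0020, 0x000D, "UI", studyUID),
    .dcmElement(0x0020, 0x000E, "UI", seriesUID),
    .dcmElement(0x0020, 0x0013, "IS", as.character(instanceNumber)),
    .dcmElement(0x0020, 0x0032, "DS", paste(.fmtDS(imagePosition), collapse = "\\")),
    .dcmElement(0x0020, 0x0037, "DS", paste(.fmtDS(imageOrientation), collapse = "\\")),
    .dcmElement(0x0028, 0x0002, "US", 1L),
    .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmElement(0x0028, 0x0010, "US", nrow(pixels)),
    .dcmElement(0x0028, 0x0011, "US", ncol(pixels)),
    .dcmElement(0x0028, 0x0030, "DS",
                paste(.fmtDS(c(geom@pixelSpacingRow, geom@pixelSpacingCol)),
                      collapse = "\\")),
    .dcmElement(0x0028, 0x0100, "US", 16L),
    .dcmElement(0x0028, 0x0101, "US", 16L),
    .dcmElement(0x0028, 0x0102, "US", 15L),
    .dcmElement(0x0028, 0x0103, "US", 0L)
  )
  pix <- as.integer(round(t(pixels)))  # row-major pixel order
  if (any(pix < 0) || any(pix > 65535))
    stop("pixel intensities must be in [0, 65535]")
  body <- c(body, .dcmElement(0x7FE0, 0x0010, "OW",
                              writeBin(pix, raw(), size = 2, endian = "little")))

  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcmElement(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    .dcmElement(0x0002, 0x0003, "UI", sopInstanceUID),
    .dcmElement(0x0002, 0x0010, "UI", .DICOM_EXPLICIT_LE),
    .dcmElement(0x0002, 0x0012, "UI", paste0(.UID_ROOT, ".1"))
  )
  meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse one DICOM file into a named list of elements keyed "GGGG,EEEE".
.readDicomFile <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(bytes)
  elems <- list()
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported encoding (expected explicit VR little endian): ", path)
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (vr == "SQ") stop("sequences are not supported: ", path)
    if (len > 0 && vstart + len - 1L > n) stop("truncated DICOM element in ", path)
    vraw <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    val <- switch(vr,
      US = readBin(vraw, integer(), n = len / 2L, size = 2, signed = FALSE,
                   endian = "little"),
      UL = readBin(vraw, integer(), n = len / 4L, size = 4, endian = "little"),
      OW = vraw, OB = vraw,
      {
        s <- rawToChar(vraw[vraw != as.raw(0x00)])  # drop NUL padding (UI)
        sub(" +$", "", s)
      })
    elems[[key]] <- list(vr = vr, value = val)
    pos <- vstart + len
  }
  elems
}

.dsValues <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  as.numeric(strsplit(e$value, "\\", fixed = TRUE)[[1]])
}

.strValue <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) NULL else e$value
}

.usValue <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) NULL else e$value[1]
}
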