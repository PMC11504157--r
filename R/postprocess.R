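# Mask inpainting: binarise -> fill holes -> despeckle -> split L/R.
# Connectivity pair: 4-connectivity for hole detection, 8-connectivity
# for foreground components (the standard complementary pair).

.shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1, 1 + dr); r2 <- min(nr, nr + dr)
  c1 <- max(1, 1 + dc); c2 <- min(nc, nc + dc)
  if (r1 > r2 || c1 > c2) return(out)
  out[r1:r2, c1:c2] <- m[(r1:r2) - dr, (c1:c2) - dc]
  out
}

.N4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
.N8 <- c(.N4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))

# Connected-component labeling by iterative minimum-label propagation.
# Returns an integer matrix, 0 = background, components numbered 1..k.
.labelComponents <- function(mask, connectivity = 8) {
  nbrs <- if (connectivity == 8) .N8 else .N4
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  fg <- mask != 0
  lab[fg] <- which(fg)
  repeat {
    new <- lab
    for (d in nbrs) new <- pmin(new, .shiftMat(lab, d[1], d[2], Inf))
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  out[fg] <- match(lab[fg], sort(unique(lab[fg])))
  out
}

#' Binarise a grayscale or probability mask
#'
#' Accepts either 0-255 grayscale values or probabilities in [0, 1]
#' (detected from the value range) and applies the single pipeline-wide
#' cut: probability >= 0.5, equivalently grayscale >= 128 on integer
#' values (127 maps to 0, 128 to 1).
#'
#' @param x numeric matrix, values in [0, 255] or [0, 1].
#' @return binary matrix.
#' @export
binarizeMask <- function(x) {
  if (!is.numeric(x)) stop("domain error: mask must be numeric")
  mx <- suppressWarnings(max(x))
  if (any(x < 0) || mx > 255)
    stop("domain error: values must lie in [0, 1] or [0, 255]")
  p <- if (mx > 1) x / 255 else x
  (p >= 0.5) * 1
}

#' Fill enclosed holes in a binary mask
#'
#' Background components not 4-connected to the image border are set to
#' foreground; foreground is never removed.
#'
#' @param mask binary matrix.
#' @return binary matrix with holes filled.
#' @export
fillHoles <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("domain error: mask must be binary")
  bg <- mask == 0
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, ncol(mask)] <- reach[, ncol(mask)] | bg[, ncol(mask)]
  repeat {
    new <- reach
    for (d in .N4) new <- new | .shiftMat(reach, d[1], d[2], FALSE)
    new <- new & bg
    if (identical(new, reach)) break
    reach <- new
  }
  out <- mask
  out[bg & !reach] <- 1
  out
}

#' Remove small foreground components
#'
#' Deletes 8-connected foreground components with area strictly below
#' \code{minSizePx}; larger components are untouched.
#'
#' @param mask binary matrix.
#' @param minSizePx minimum component area (pixels) to keep; default 25
#'   on the native grid.
#' @return binary matrix.
#' @export
despeckle <- function(mask, minSizePx = 25) {
  if (!all(mask %in% c(0, 1))) stop("domain error: mask must be binary")
  if (minSizePx < 0) stop("domain error: minSizePx must be >= 0")
  if (minSizePx <= 1 || sum(mask) == 0) return(mask)
  lab <- .labelComponents(mask, 8)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSizePx)
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1
}

#' Separate left and right kidneys
#'
#' Per slice, 8-connected foreground components are assigned by the
#' column of their centroid relative to the image vertical midline.
#' Radiological convention: components left of the midline on the image
#' are the patient's right kidney; components at or right of the midline
#' (ties included) are the patient's left kidney. A component straddling
#' the midline is assigned wholly by its centroid. A warning is emitted
#' when occupancy flips sides between adjacent slices.
#'
#' @param masks list of cleaned binary matrices, one per slice (empty
#'   slices allowed).
#' @param geom the \linkS4class{SeriesGeometry} of the series.
#' @return a \linkS4class{LateralizedMaskStack}.
#' @export
splitLeftRight <- function(masks, geom) {
  mid <- (geom@nCols - 1) / 2  # 0-based center column
  left <- vector("list", length(masks))
  right <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    L <- matrix(0, nrow(m), ncol(m)); R <- L
    if (sum(m) > 0) {
      lab <- .labelComponents(m, 8)
      for (k in seq_len(max(lab))) {
        idx <- which(lab == k)
        colsk <- (idx - 1) %/% nrow(m)  # 0-based columns
        if (mean(colsk) < mid) R[idx] <- 1 else L[idx] <- 1
      }
    }
    left[[i]] <- L; right[[i]] <- R
  }
  occ <- function(lst) vapply(lst, function(x) sum(x) > 0, logical(1))
  ol <- occ(left); or <- occ(right)
  for (i in seq_along(masks)[-1]) {
    if ((ol[i - 1] && !ol[i] && !or[i - 1] && or[i]) ||
        (or[i - 1] && !or[i] && !ol[i - 1] && ol[i]))
      warning(sprintf("laterality flipped between slices %d and %d", i - 1, i))
  }
  new("LateralizedMaskStack", left = left, right = right, geometry = geom)
}

#' Full mask inpainting pipeline
#'
#' Applies the fixed stage order binarise -> fill holes -> despeckle ->
#' split left/right (filling before despeckling preserves ring-shaped
#' cross-sections that would otherwise fall below the size cut).
#'
#' @param rawMasks list of per-slice model outputs (probabilities in
#'   [0, 1] or grayscale 0-255) on the native grid.
#' @param geom the \linkS4class{SeriesGeometry}.
#' @param minSizePx despeckle threshold in pixels (default 25).
#' @return a \linkS4class{LateralizedMaskStack}.
#' @export
postprocessStack <- function(rawMasks, geom, minSizePx = 25) {
  cleaned <- lapply(rawMasks, function(m)
    despeckle(fillHoles(binarizeMask(m)), minSizePx))
  splitLeftRight(cleaned, geom)
}

#' Read / write binary masks as 8-bit PNG
#'
#' Foreground is written as 255, background as 0. Reading binarises at
#' the pipeline cut, so grayscale PNGs round-trip through
#' [binarizeMask()] semantics.
#'
#' @param mask binary matrix.
#' @param path PNG file path.
#' @return \code{writeMaskPng}: invisibly, \code{path};
#'   \code{readMaskPng}: a binary matrix.
#' @export
writeMaskPng <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("domain error: mask must be binary")
  storage.mode(mask) <- "double"  # writePNG rejects integer storage
  png::writePNG(mask, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m >= 0.5) * 1
}
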