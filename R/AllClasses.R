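#' @import methods
NULL

#' SeriesGeometry: spatial metadata of one imaging series
#'
#' Holds the per-series geometric metadata that volumetry depends on:
#' in-plane pixel spacing (mm/pixel along rows and columns), slice
#' thickness (mm), the optional spacing between slices (mm, \code{NA}
#' when the series does not carry the tag), the pixel grid size and the
#' anatomical orientation of the slices.
#'
#' @slot pixelSpacingRow mm per pixel along the row (vertical) direction.
#' @slot pixelSpacingCol mm per pixel along the column (horizontal) direction.
#' @slot sliceThickness slice thickness in mm.
#' @slot spacingBetweenSlices centre-to-centre slice distance in mm, or
#'   \code{NA_real_} when absent from the series.
#' @slot nRows,nCols pixel grid dimensions.
#' @slot orientation \code{"axial"} or \code{"coronal"}.
#'
#' @exportClass SeriesGeometry
setClass("SeriesGeometry",
  representation(
    pixelSpacingRow = "numeric",
    pixelSpacingCol = "numeric",
    sliceThickness = "numeric",
    spacingBetweenSlices = "numeric",
    nRows = "integer",
    nCols = "integer",
    orientation = "character"
  )
)

setValidity("SeriesGeometry", function(object) {
  msg <- character()
  sp <- c(object@pixelSpacingRow, object@pixelSpacingCol, object@sliceThickness)
  if (length(object@pixelSpacingRow) != 1L || length(object@pixelSpacingCol) != 1L ||
      length(object@sliceThickness) != 1L || length(object@spacingBetweenSlices) != 1L)
    msg <- c(msg, "all spacing slots must be length 1")
  else {
    if (any(!is.finite(sp)) || any(sp <= 0))
      msg <- c(msg, "pixel spacings and slice thickness must be strictly positive")
    if (!is.na(object@spacingBetweenSlices) && object@spacingBetweenSlices <= 0)
      msg <- c(msg, "spacingBetweenSlices must be strictly positive when present")
  }
  if (length(object@nRows) != 1L || length(object@nCols) != 1L ||
      is.na(object@nRows) || is.na(object@nCols) ||
      object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (length(object@orientation) != 1L ||
      !object@orientation %in% c("axial", "coronal"))
    msg <- c(msg, "orientation must be 'axial' or 'coronal'")
  if (length(msg)) msg else TRUE
})

#' Construct a SeriesGeometry
#'
#' @param pixelSpacingRow,pixelSpacingCol in-plane spacing, mm per pixel.
#' @param sliceThickness slice thickness, mm.
#' @param spacingBetweenSlices centre-to-centre slice distance, mm;
#'   \code{NA} (default) means the series does not state it.
#' @param nRows,nCols pixel grid dimensions.
#' @param orientation \code{"axial"} or \code{"coronal"}.
#' @return A \linkS4class{SeriesGeometry} object.
#' @examples
#' seriesGeometry(1.5, 1.5, 5, nRows = 256, nCols = 256)
#' @export
seriesGeometry <- function(pixelSpacingRow, pixelSpacingCol, sliceThickness,
                           spacingBetweenSlices = NA_real_,
                           nRows, nCols, orientation = "axial") {
  new("SeriesGeometry",
      pixelSpacingRow = as.numeric(pixelSpacingRow),
      pixelSpacingCol = as.numeric(pixelSpacingCol),
      sliceThickness = as.numeric(sliceThickness),
      spacingBetweenSlices = as.numeric(spacingBetweenSlices),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      orientation = orientation)
}

#' SliceStack: an ordered grayscale imaging series
#'
#' An ordered list of 2D grayscale slices (integer-valued matrices,
#' intensities >= 0) together with the series geometry, an opaque subject
#' identifier and optional physical slice positions (mm along the
#' stacking axis).
#'
#' @slot slices list of numeric matrices, each of dim
#'   \code{(nRows, nCols)}.
#' @slot geometry a \linkS4class{SeriesGeometry}.
#' @slot subjectId character scalar.
#' @slot slicePositions numeric vector of positions in mm (may be all
#'   \code{NA} when unknown); when present, slice order is monotone in
#'   position.
#'
#' @exportClass SliceStack
setClass("SliceStack",
  representation(
    slices = "list",
    geometry = "SeriesGeometry",
    subjectId = "character",
    slicePositions = "numeric"
  )
)

setValidity("SliceStack", function(object) {
  msg <- character()
  n <- length(object@slices)
  if (n < 1L) msg <- c(msg, "a SliceStack needs at least one slice")
  g <- object@geometry
  okdim <- vapply(object@slices, function(s)
    is.matrix(s) && nrow(s) == g@nRows && ncol(s) == g@nCols, logical(1))
  if (!all(okdim))
    msg <- c(msg, sprintf("every slice must be a %d x %d matrix", g@nRows, g@nCols))
  if (length(object@slicePositions) != n)
    msg <- c(msg, "slicePositions must have one entry per slice")
  pos <- object@slicePositions
  if (!anyNA(pos) && n > 1L) {
    d <- diff(pos)
    if (!(all(d >= 0) || all(d <= 0)))
      msg <- c(msg, "slice order must be monotone in position")
  }
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceStack
#'
#' @param slices list of numeric matrices of dim \code{(nRows, nCols)}.
#' @param geometry a \linkS4class{SeriesGeometry}.
#' @param subjectId subject identifier.
#' @param slicePositions optional numeric positions (mm) along the
#'   stacking axis; defaults to \code{NA}.
#' @return A \linkS4class{SliceStack}.
#' @export
sliceStack <- function(slices, geometry, subjectId = "unknown",
                       slicePositions = rep(NA_real_, length(slices))) {
  new("SliceStack", slices = slices, geometry = geometry,
      subjectId = subjectId, slicePositions = as.numeric(slicePositions))
}

#' LateralizedMaskStack: left/right kidney masks for one series
#'
#' Per-slice binary masks split by anatomical side. Left and right are
#' disjoint on every slice and share the series geometry.
#'
#' @slot left,right lists of binary matrices (one per slice).
#' @slot geometry a \linkS4class{SeriesGeometry}.
#' @exportClass LateralizedMaskStack
setClass("LateralizedMaskStack",
  representation(left = "list", right = "list", geometry = "SeriesGeometry")
)

setValidity("LateralizedMaskStack", function(object) {
  msg <- character()
  if (length(object@left) != length(object@right))
    msg <- c(msg, "left and right must have the same number of slices")
  else {
    for (i in seq_along(object@left)) {
      l <- object@left[[i]]; r <- object@right[[i]]
      if (!identical(dim(l), dim(r))) {
        msg <- c(msg, "left/right slice dimensions differ"); break
      }
      if (!all(l %in% c(0, 1)) || !all(r %in% c(0, 1))) {
        msg <- c(msg, "masks must be binary"); break
      }
      if (any(l * r != 0)) {
        msg <- c(msg, sprintf("left and right overlap on slice %d", i)); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' KidneyVolumes: per-kidney and total volume for one subject
#'
#' @slot leftMl,rightMl,totalMl volumes in millilitres;
#'   \code{totalMl == leftMl + rightMl}.
#' @slot method \code{"planimetric"} or \code{"midslice"}.
#' @slot subjectId subject identifier.
#' @exportClass KidneyVolumes
setClass("KidneyVolumes",
  representation(leftMl = "numeric", rightMl = "numeric", totalMl = "numeric",
                 method = "character", subjectId = "character")
)

setValidity("KidneyVolumes", function(object) {
  msg <- character()
  v <- c(object@leftMl, object@rightMl, object@totalMl)
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "volumes must be finite and >= 0")
  if (abs(object@totalMl - (object@leftMl + object@rightMl)) >
      1e-8 * max(1, object@totalMl))
    msg <- c(msg, "totalMl must equal leftMl + rightMl")
  if (!object@method %in% c("planimetric", "midslice"))
    msg <- c(msg, "method must be 'planimetric' or 'midslice'")
  if (length(msg)) msg else TRUE
})

kidneyVolumes <- function(leftMl, rightMl, method, subjectId = "unknown") {
  new("KidneyVolumes", leftMl = leftMl, rightMl = rightMl,
      totalMl = leftMl + rightMl, method = method, subjectId = subjectId)
}

#' PhantomCase: one synthetic MRI case with known ground truth
#'
#' @slot stack the rendered \linkS4class{SliceStack}.
#' @slot truth ground-truth kidney masks as a
#'   \linkS4class{LateralizedMaskStack} (noise-free, cysts counted as
#'   kidney).
#' @slot trueVolumes voxel-counted volumes (\linkS4class{KidneyVolumes}).
#' @slot analyticVolumes closed-form ellipsoid volumes
#'   \eqn{4/3\,\pi\,abc} per side (\linkS4class{KidneyVolumes}).
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(stack = "SliceStack", truth = "LateralizedMaskStack",
                 trueVolumes = "KidneyVolumes",
                 analyticVolumes = "KidneyVolumes")
)
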