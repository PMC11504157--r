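# Pixel counts -> physical areas -> millilitre volumes.

.sliceSpacing <- function(geom, spacingMode) {
  switch(spacingMode,
    thickness = geom@sliceThickness,
    between_slices = {
      if (is.na(geom@spacingBetweenSlices))
        stop("metadata error: SpacingBetweenSlices absent; cannot use ",
             "spacingMode = 'between_slices'")
      geom@spacingBetweenSlices
    },
    stop("spacingMode must be 'thickness' or 'between_slices'"))
}

#' Cross-sectional area of one mask slice
#'
#' Area (mm^2) = foreground pixel count x pixelSpacingRow x
#' pixelSpacingCol.
#'
#' @param mask binary matrix on the native grid.
#' @param geom the \linkS4class{SeriesGeometry}.
#' @return area in mm^2.
#' @examples
#' g <- seriesGeometry(1.5, 1.5, 5, nRows = 64, nCols = 64)
#' m <- matrix(0, 64, 64); m[1:25, 1:40] <- 1
#' sliceAreaMm2(m, g)  # 1000 px * 2.25 mm^2
#' @export
sliceAreaMm2 <- function(mask, geom) {
  if (nrow(mask) != geom@nRows || ncol(mask) != geom@nCols)
    stop("shape error: mask does not match the series grid")
  sum(mask != 0) * geom@pixelSpacingRow * geom@pixelSpacingCol
}

#' Planimetric volume of one kidney
#'
#' Sums per-slice cross-sectional areas times the through-plane spacing:
#' volume (mL) = sum(area_mm2) x delta / 1000, with delta = slice
#' thickness (default) or the spacing between slices.
#'
#' @param masks list of binary matrices, one per slice (empty slices
#'   contribute zero).
#' @param geom the \linkS4class{SeriesGeometry}.
#' @param spacingMode \code{"thickness"} (default) or
#'   \code{"between_slices"}.
#' @return volume in millilitres.
#' @export
kidneyVolumeMl <- function(masks, geom, spacingMode = c("thickness", "between_slices")) {
  spacingMode <- match.arg(spacingMode)
  delta <- .sliceSpacing(geom, spacingMode)
  if (!is.na(geom@spacingBetweenSlices) &&
      abs(geom@spacingBetweenSlices - geom@sliceThickness) >
      0.05 * geom@sliceThickness)
    message(sprintf(paste0("slice thickness (%g mm) and spacing between slices",
                           " (%g mm) differ by > 5%%; using %s"),
                    geom@sliceThickness, geom@spacingBetweenSlices, spacingMode))
  areas <- vapply(masks, sliceAreaMm2, numeric(1), geom = geom)
  sum(areas) * delta / 1000
}

#' Planimetric total kidney volume
#'
#' Per-side planimetric volumes summed into TKV.
#'
#' @param leftMasks,rightMasks aligned per-slice mask lists (or a
#'   \linkS4class{LateralizedMaskStack} passed as \code{leftMasks}).
#' @param geom the \linkS4class{SeriesGeometry} (taken from the stack
#'   when a \linkS4class{LateralizedMaskStack} is given).
#' @param spacingMode through-plane spacing choice, see
#'   [kidneyVolumeMl()].
#' @param subjectId identifier for the report.
#' @return a \linkS4class{KidneyVolumes} with \code{method =
#'   "planimetric"}.
#' @export
totalKidneyVolume <- function(leftMasks, rightMasks = NULL, geom = NULL,
                              spacingMode = c("thickness", "between_slices"),
                              subjectId = "unknown") {
  spacingMode <- match.arg(spacingMode)
  if (is(leftMasks, "LateralizedMaskStack")) {
    stk <- leftMasks
    leftMasks <- stk@left; rightMasks <- stk@right; geom <- stk@geometry
  }
  if (length(leftMasks) != length(rightMasks))
    stop("input error: left and right stacks are not aligned")
  kidneyVolumes(kidneyVolumeMl(leftMasks, geom, spacingMode),
                kidneyVolumeMl(rightMasks, geom, spacingMode),
                method = "planimetric", subjectId = subjectId)
}

.midsliceOne <- function(masks, geom, delta) {
  areas <- vapply(masks, sliceAreaMm2, numeric(1), geom = geom)
  S <- which(areas > 0)
  if (length(S) == 0) return(0)
  m <- S[floor((length(S) + 1) / 2)]  # lower median for even counts
  areas[m] * length(S) * delta / 1000
}

#' Mid-slice total kidney volume
#'
#' The uncorrected mid-slice approximation: per kidney, the area of the
#' middle kidney-bearing slice (lower median index for even counts)
#' times the number of kidney-bearing slices times the through-plane
#' spacing. For an ellipsoid this overestimates the planimetric volume
#' by a factor approaching 3/2 (pi*a*b*2c vs 4/3*pi*a*b*c).
#'
#' @inheritParams totalKidneyVolume
#' @return a \linkS4class{KidneyVolumes} with \code{method =
#'   "midslice"}.
#' @export
midsliceTkv <- function(leftMasks, rightMasks = NULL, geom = NULL,
                        spacingMode = c("thickness", "between_slices"),
                        subjectId = "unknown") {
  spacingMode <- match.arg(spacingMode)
  if (is(leftMasks, "LateralizedMaskStack")) {
    stk <- leftMasks
    leftMasks <- stk@left; rightMasks <- stk@right; geom <- stk@geometry
  }
  if (length(leftMasks) != length(rightMasks))
    stop("input error: left and right stacks are not aligned")
  delta <- .sliceSpacing(geom, spacingMode)
  kidneyVolumes(.midsliceOne(leftMasks, geom, delta),
                .midsliceOne(rightMasks, geom, delta),
                method = "midslice", subjectId = subjectId)
}
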