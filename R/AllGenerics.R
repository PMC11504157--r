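# Accessors and show methods for the core containers.

#' @name SeriesGeometry-accessors
#' @title Accessors for SeriesGeometry
#' @param object a \linkS4class{SeriesGeometry} (or an object carrying one).
#' @return the requested metadata field.
NULL

#' @describeIn SeriesGeometry-accessors mm per pixel along rows.
#' @export
setGeneric("pixelSpacingRow", function(object) standardGeneric("pixelSpacingRow"))
#' @describeIn SeriesGeometry-accessors mm per pixel along columns.
#' @export
setGeneric("pixelSpacingCol", function(object) standardGeneric("pixelSpacingCol"))
#' @describeIn SeriesGeometry-accessors slice thickness (mm).
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))
#' @describeIn SeriesGeometry-accessors spacing between slices (mm, NA when absent).
#' @export
setGeneric("spacingBetweenSlices", function(object) standardGeneric("spacingBetweenSlices"))
#' @describeIn SeriesGeometry-accessors orientation label.
#' @export
setGeneric("orientation", function(object) standardGeneric("orientation"))
#' @describeIn SeriesGeometry-accessors the series geometry of a compound object.
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @describeIn SeriesGeometry-accessors subject identifier.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' Slices of a SliceStack
#' @param object a \linkS4class{SliceStack}.
#' @return list of slice matrices.
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))
#' Left-side masks
#' @param object a \linkS4class{LateralizedMaskStack}.
#' @return list of binary matrices.
#' @export
setGeneric("leftMasks", function(object) standardGeneric("leftMasks"))
#' Right-side masks
#' @param object a \linkS4class{LateralizedMaskStack}.
#' @return list of binary matrices.
#' @export
setGeneric("rightMasks", function(object) standardGeneric("rightMasks"))
#' Volumes in millilitres
#' @param object a \linkS4class{KidneyVolumes}.
#' @return numeric scalar (mL).
#' @export
setGeneric("leftMl", function(object) standardGeneric("leftMl"))
#' @rdname leftMl
#' @export
setGeneric("rightMl", function(object) standardGeneric("rightMl"))
#' @rdname leftMl
#' @export
setGeneric("totalMl", function(object) standardGeneric("totalMl"))

#' @rdname SeriesGeometry-accessors
#' @export
setMethod("pixelSpacingRow", "SeriesGeometry", function(object) object@pixelSpacingRow)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("pixelSpacingCol", "SeriesGeometry", function(object) object@pixelSpacingCol)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("sliceThickness", "SeriesGeometry", function(object) object@sliceThickness)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("spacingBetweenSlices", "SeriesGeometry", function(object) object@spacingBetweenSlices)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("orientation", "SeriesGeometry", function(object) object@orientation)

setMethod("dim", "SeriesGeometry", function(x) c(x@nRows, x@nCols))

#' @rdname SeriesGeometry-accessors
#' @export
setMethod("geometry", "SliceStack", function(object) object@geometry)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("geometry", "LateralizedMaskStack", function(object) object@geometry)
#' @rdname SeriesGeometry-accessors
#' @export
setMethod("subjectId", "SliceStack", function(object) object@subjectId)

#' @rdname slices
#' @export
setMethod("slices", "SliceStack", function(object) object@slices)
setMethod("length", "SliceStack", function(x) length(x@slices))
setMethod("length", "LateralizedMaskStack", function(x) length(x@left))

#' @rdname leftMasks
#' @export
setMethod("leftMasks", "LateralizedMaskStack", function(object) object@left)
#' @rdname rightMasks
#' @export
setMethod("rightMasks", "LateralizedMaskStack", function(object) object@right)

#' @rdname leftMl
#' @export
setMethod("leftMl", "KidneyVolumes", function(object) object@leftMl)
#' @rdname leftMl
#' @export
setMethod("rightMl", "KidneyVolumes", function(object) object@rightMl)
#' @rdname leftMl
#' @export
setMethod("totalMl", "KidneyVolumes", function(object) object@totalMl)

#' Accessors for PhantomCase
#' @param object a \linkS4class{PhantomCase}.
#' @return the requested component.
#' @export
setGeneric("phantomStack", function(object) standardGeneric("phantomStack"))
#' @rdname phantomStack
#' @export
setGeneric("truthMasks", function(object) standardGeneric("truthMasks"))
#' @rdname phantomStack
#' @export
setGeneric("trueVolumes", function(object) standardGeneric("trueVolumes"))
#' @rdname phantomStack
#' @export
setGeneric("analyticVolumes", function(object) standardGeneric("analyticVolumes"))
#' @rdname phantomStack
#' @export
setMethod("phantomStack", "PhantomCase", function(object) object@stack)
#' @rdname phantomStack
#' @export
setMethod("truthMasks", "PhantomCase", function(object) object@truth)
#' @rdname phantomStack
#' @export
setMethod("trueVolumes", "PhantomCase", function(object) object@trueVolumes)
#' @rdname phantomStack
#' @export
setMethod("analyticVolumes", "PhantomCase", function(object) object@analyticVolumes)

setMethod("show", "SeriesGeometry", function(object) {
  cat("SeriesGeometry:", object@nRows, "x", object@nCols, object@orientation, "\n")
  cat("  pixel spacing (row x col): ", object@pixelSpacingRow, " x ",
      object@pixelSpacingCol, " mm\n", sep = "")
  cat("  slice thickness: ", object@sliceThickness, " mm; spacing between slices: ",
      ifelse(is.na(object@spacingBetweenSlices), "absent",
             paste0(object@spacingBetweenSlices, " mm")), "\n", sep = "")
})

setMethod("show", "SliceStack", function(object) {
  cat("SliceStack '", object@subjectId, "': ", length(object@slices),
      " slice(s)\n", sep = "")
  show(object@geometry)
})

setMethod("show", "LateralizedMaskStack", function(object) {
  nl <- sum(vapply(object@left, sum, numeric(1)))
  nr <- sum(vapply(object@right, sum, numeric(1)))
  cat("LateralizedMaskStack: ", length(object@left), " slice(s); foreground px",
      " left ", nl, ", right ", nr, "\n", sep = "")
})

setMethod("show", "KidneyVolumes", function(object) {
  cat(sprintf("KidneyVolumes [%s, %s]: left %.1f mL, right %.1f mL, total %.1f mL\n",
              object@subjectId, object@method, object@leftMl, object@rightMl,
              object@totalMl))
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase '", object@stack@subjectId, "'\n", sep = "")
  show(object@stack@geometry)
  cat(sprintf("  true TKV %.1f mL (analytic %.1f mL)\n",
              object@trueVolumes@totalMl, object@analyticVolumes@totalMl))
})
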