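# Polygon annotations -> masks, train/validation splitting, and
# per-epoch random augmentation of (image, mask) pairs.

.KIDNEY_LABELS <- c("left_kidney", "right_kidney")

# Run expr with a temporarily seeded RNG, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Construct a polygon annotation
#'
#' @param label \code{"left_kidney"} or \code{"right_kidney"}.
#' @param vertices numeric matrix with columns (x = pixel column,
#'   y = pixel row), 0-based pixel-center coordinates; at least 3 rows.
#' @param imageRef identifier of the annotated slice.
#' @param shape optional \code{c(nRows, nCols)}; when given, vertices are
#'   clipped to the image bounds.
#' @return a \code{PolygonAnnotation} (validated list).
#' @export
polygonAnnotation <- function(label, vertices, imageRef = "", shape = NULL) {
  if (!label %in% .KIDNEY_LABELS)
    stop("annotation error: label must be one of ",
         paste(.KIDNEY_LABELS, collapse = ", "))
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    stop("annotation error: polygon needs at least 3 vertices")
  if (ncol(vertices) != 2) stop("annotation error: vertices must be (x, y) pairs")
  if (!is.null(shape)) {
    vertices[, 1] <- pmin(pmax(vertices[, 1], 0), shape[2] - 1)
    vertices[, 2] <- pmin(pmax(vertices[, 2], 0), shape[1] - 1)
  }
  structure(list(label = label, vertices = vertices, imageRef = imageRef),
            class = "PolygonAnnotation")
}

# Even-odd point-in-polygon over all pixel centers, boundary inclusive.
.rasterizePolygon <- function(vertices, shape, tol = 1e-9) {
  nr <- shape[1]; nc <- shape[2]
  px <- rep(0:(nc - 1), each = nr)   # x = column, column-major grid
  py <- rep(0:(nr - 1), times = nc)  # y = row
  crossings <- integer(nr * nc)
  onEdge <- logical(nr * nc)
  v <- vertices
  nv <- nrow(v)
  for (k in seq_len(nv)) {
    a <- v[k, ]; b <- v[if (k == nv) 1L else k + 1L, ]
    x1 <- a[1]; y1 <- a[2]; x2 <- b[1]; y2 <- b[2]
    # edge crossing of the rightward horizontal ray from each center
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xi <- x1 + (py[straddles] - y1) * (x2 - x1) / (y2 - y1)
      hit <- straddles
      hit[straddles] <- px[straddles] < xi
      crossings <- crossings + hit
    }
    # boundary: distance from center to segment ab
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    onEdge <- onEdge | d2 <= tol
  }
  matrix(as.numeric((crossings %% 2 == 1) | onEdge), nr, nc)
}

#' Rasterise polygon annotations into a binary mask
#'
#' A pixel is foreground iff its center lies inside (even-odd rule) or on
#' the boundary of any polygon. Left and right kidney polygons are merged
#' into a single foreground mask (the training target); the per-side
#' labels remain available through the annotations themselves.
#'
#' @param annotations list of \code{PolygonAnnotation} objects (possibly
#'   empty).
#' @param shape \code{c(nRows, nCols)} of the target mask.
#' @return binary \code{nRows x nCols} matrix.
#' @examples
#' rect <- polygonAnnotation("left_kidney",
#'   cbind(c(10, 19, 19, 10), c(10, 10, 19, 19)))
#' sum(polygonsToMask(list(rect), c(64, 64)))  # 100
#' @export
polygonsToMask <- function(annotations, shape) {
  if (any(shape < 1)) stop("input error: shape must be positive")
  mask <- matrix(0, shape[1], shape[2])
  for (ann in annotations) {
    if (!inherits(ann, "PolygonAnnotation"))
      ann <- do.call(polygonAnnotation, ann)
    mask <- pmax(mask, .rasterizePolygon(ann$vertices, shape))
  }
  mask
}

#' Read a Labelme-style annotation file
#'
#' Expects the Labelme JSON layout: \code{shapes[].label},
#' \code{shapes[].points} (x, y pairs), \code{imageHeight},
#' \code{imageWidth}.
#'
#' @param path JSON file path.
#' @return list with \code{annotations} (list of
#'   \code{PolygonAnnotation}) and \code{shape} = c(nRows, nCols).
#' @export
readLabelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shape <- c(j$imageHeight, j$imageWidth)
  anns <- lapply(j$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    polygonAnnotation(s$label, pts, imageRef = if (is.null(j$imagePath)) ""
                      else j$imagePath, shape = shape)
  })
  list(annotations = anns, shape = as.integer(shape))
}

#' Write a Labelme-style annotation file
#'
#' @param annotations list of \code{PolygonAnnotation}.
#' @param shape image \code{c(nRows, nCols)}.
#' @param path output JSON path.
#' @param imagePath value for the \code{imagePath} field.
#' @return invisibly, \code{path}.
#' @export
writeLabelme <- function(annotations, shape, path, imagePath = "") {
  shapes <- lapply(annotations, function(a) {
    list(label = a$label,
         points = lapply(seq_len(nrow(a$vertices)),
                         function(i) as.numeric(a$vertices[i, ])),
         group_id = NULL, shape_type = "polygon", flags = structure(list(), names = character(0)))
  })
  obj <- list(version = "3.0", flags = structure(list(), names = character(0)),
              shapes = shapes, imagePath = imagePath, imageData = NULL,
              imageHeight = shape[1], imageWidth = shape[2])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic train/validation split
#'
#' Splits items into train and validation sets with
#' \code{floor(n * trainFrac)} training items. \code{by = "image"}
#' permutes individual items (the default); \code{by = "patient"} splits
#' whole subjects so no subject contributes to both sets.
#'
#' @param items list (or vector) of items to split.
#' @param trainFrac training fraction in (0, 1); default 0.8.
#' @param seed integer seed making the split reproducible.
#' @param by \code{"image"} or \code{"patient"}.
#' @param subjectIds subject of each item (required for
#'   \code{by = "patient"}).
#' @return list with elements \code{train}, \code{validation},
#'   \code{trainIdx}, \code{validationIdx}.
#' @examples
#' s <- splitTrainVal(seq_len(1483), 0.8, seed = 1)
#' length(s$train)       # 1186
#' length(s$validation)  # 297
#' @export
splitTrainVal <- function(items, trainFrac = 0.8, seed = 1L,
                          by = c("image", "patient"), subjectIds = NULL) {
  by <- match.arg(by)
  n <- length(items)
  if (n == 0) stop("input error: no items to split")
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("input error: trainFrac must be in (0, 1)")
  if (by == "image") {
    perm <- .withSeed(seed, sample.int(n))
    k <- floor(n * trainFrac)
    trIdx <- sort(perm[seq_len(k)])
  } else {
    if (is.null(subjectIds) || length(subjectIds) != n)
      stop("input error: by='patient' needs one subjectId per item")
    subj <- unique(subjectIds)
    perm <- .withSeed(seed, sample(subj))
    k <- floor(length(subj) * trainFrac)
    trSubj <- perm[seq_len(k)]
    trIdx <- which(subjectIds %in% trSubj)
  }
  vaIdx <- setdiff(seq_len(n), trIdx)
  list(train = items[trIdx], validation = items[vaIdx],
       trainIdx = trIdx, validationIdx = vaIdx)
}

#' Augmentation parameters
#'
#' Magnitudes of the per-epoch random augmentation: rotation (degrees),
#' shift (fraction of each dimension), zoom (fraction), optional flips
#' (disabled by default, matching the training protocol).
#'
#' @param rotationMaxDeg max |rotation| in degrees (default 5).
#' @param shiftMaxFrac max |shift| as a fraction of the dimension
#'   (default 0.10).
#' @param zoomMaxFrac max zoom deviation from 1 (default 0.10).
#' @param horizontalFlip,verticalFlip enable random flips (default FALSE).
#' @param seed optional integer seed for draw streams.
#' @return an \code{AugmentationParams} (validated list).
#' @export
augmentationParams <- function(rotationMaxDeg = 5, shiftMaxFrac = 0.10,
                               zoomMaxFrac = 0.10, horizontalFlip = FALSE,
                               verticalFlip = FALSE, seed = NULL) {
  stopifnot(rotationMaxDeg >= 0, shiftMaxFrac >= 0, zoomMaxFrac >= 0)
  structure(list(rotationMaxDeg = rotationMaxDeg, shiftMaxFrac = shiftMaxFrac,
                 zoomMaxFrac = zoomMaxFrac, horizontalFlip = horizontalFlip,
                 verticalFlip = verticalFlip, seed = seed),
            class = "AugmentationParams")
}

# Draw one set of transform parameters from the current RNG stream.
.drawAugment <- function(params) {
  list(rot = stats::runif(1, -params$rotationMaxDeg, params$rotationMaxDeg),
       shiftR = stats::runif(1, -params$shiftMaxFrac, params$shiftMaxFrac),
       shiftC = stats::runif(1, -params$shiftMaxFrac, params$shiftMaxFrac),
       zoom = stats::runif(1, 1 - params$zoomMaxFrac, 1 + params$zoomMaxFrac),
       flipH = params$horizontalFlip && stats::runif(1) < 0.5,
       flipV = params$verticalFlip && stats::runif(1) < 0.5)
}

#' Apply one random augmentation to an (image, mask) pair
#'
#' Draws rotation ~ U(-r, r) degrees, per-axis shifts ~ U(-s, s) times
#' the dimension, and zoom ~ U(1-z, 1+z), and applies the same affine
#' transform (about the image center) to image and mask. The image is
#' interpolated bilinearly, the mask nearest-neighbour and re-binarised;
#' regions mapped from outside the canvas are filled with 0 (dark MRI
#' background). Degenerate (all-zero) parameters return the pair
#' unchanged.
#'
#' @param pair list with elements \code{image} (matrix in [0,1]) and
#'   \code{mask} (binary matrix of the same shape); extra elements are
#'   passed through.
#' @param params an [augmentationParams()] object.
#' @param draw optional pre-drawn transform (list with \code{rot},
#'   \code{shiftR}, \code{shiftC}, \code{zoom}, \code{flipH},
#'   \code{flipV}); when \code{NULL} one is drawn from the current RNG
#'   stream.
#' @return the augmented pair (same structure).
#' @export
augmentPair <- function(pair, params, draw = NULL) {
  if (is.null(draw)) draw <- .drawAugment(params)
  H <- nrow(pair$image); W <- ncol(pair$image)
  identityTf <- draw$rot == 0 && draw$shiftR == 0 && draw$shiftC == 0 &&
    draw$zoom == 1 && !isTRUE(draw$flipH) && !isTRUE(draw$flipV)
  if (identityTf) return(pair)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  th <- draw$rot * pi / 180
  # inverse map: src = c + R(-theta) (dst - c - t) / zoom, then flips
  dstR <- rep(0:(H - 1), times = W)  # column-major over output grid
  dstC <- rep(0:(W - 1), each = H)
  ur <- (dstR - cr - draw$shiftR * H) / draw$zoom
  uc <- (dstC - cc - draw$shiftC * W) / draw$zoom
  sr <- cos(th) * ur + sin(th) * uc + cr
  sc <- -sin(th) * ur + cos(th) * uc + cc
  if (isTRUE(draw$flipH)) sc <- (W - 1) - sc
  if (isTRUE(draw$flipV)) sr <- (H - 1) - sr
  img <- .sampleAt(pair$image, sr, sc, H, W, "bilinear")
  msk <- .sampleAt(pair$mask, sr, sc, H, W, "nearest")
  pair$image <- pmin(pmax(img, 0), 1)
  pair$mask <- (msk >= 0.5) * 1
  pair
}

#' Build (image, mask) training pairs from a stack and per-slice masks
#'
#' Each slice goes through [prepareForModel()] and its mask is
#' nearest-neighbour resampled to the same model grid.
#'
#' @param stack a \linkS4class{SliceStack}.
#' @param masks list of binary matrices on the native grid, one per slice.
#' @param size model grid side (default 256).
#' @param keepEmpty keep slices whose mask is empty (default TRUE).
#' @return list of pairs: \code{image}, \code{mask}, \code{subjectId},
#'   \code{sliceIndex}.
#' @export
labeledPairs <- function(stack, masks, size = 256L, keepEmpty = TRUE) {
  stopifnot(length(masks) == length(stack@slices))
  out <- list()
  for (i in seq_along(masks)) {
    if (!keepEmpty && sum(masks[[i]]) == 0) next
    img <- prepareForModel(stack@slices[[i]], size)
    msk <- .nearestResample(masks[[i]], size, size)
    out[[length(out) + 1L]] <- list(image = img, mask = (msk >= 0.5) * 1,
                                    subjectId = stack@subjectId,
                                    sliceIndex = i)
  }
  out
}
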