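# Synthetic MRI-like phantom: two ellipsoidal kidneys with optional
# bright cysts, Gaussian noise, full geometry metadata, exact truth
# masks and analytic volumes.

#' Phantom specification
#'
#' Defines one synthetic case: grid and spacing, orientation, per-side
#' ellipsoid semiaxes and centers (mm, patient coordinates: x lateral,
#' y anteroposterior, z cranio-caudal), cyst count and size, intensity
#' levels on the 0-255 scale, and the noise level. Defaults describe a
#' small abdominal T2-like series: 64 x 64 in-plane at 4 mm, 20 slices
#' of 6 mm, kidneys of roughly physiological size placed at +/- 44 mm
#' laterally, dark background (30), kidney parenchyma 120, fluid-bright
#' cysts 220, noise SD 8.
#'
#' @param nSlices,nRows,nCols grid dimensions.
#' @param pixelSpacing in-plane spacing, mm (isotropic in-plane).
#' @param sliceThickness through-plane spacing, mm.
#' @param orientation \code{"axial"} or \code{"coronal"} (relabels the
#'   stacking axis; coronal sections show the elongated long axis
#'   in-plane).
#' @param leftSemiaxes,rightSemiaxes c(a, b, c) ellipsoid semiaxes, mm
#'   (a lateral, b anteroposterior, c cranio-caudal).
#' @param leftCenter,rightCenter c(x, y, z) ellipsoid centers, mm;
#'   patient-left is +x.
#' @param nCysts cysts per kidney.
#' @param cystRadiusRange c(min, max) cyst radius, mm.
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param backgroundIntensity,kidneyIntensity,cystIntensity levels in
#'   [0, 255].
#' @param seed integer seed; the phantom is deterministic given the
#'   spec.
#' @param subjectId identifier.
#' @return a \code{PhantomSpec} (validated list).
#' @export
phantomSpec <- function(nSlices = 20L, nRows = 64L, nCols = 64L,
                        pixelSpacing = 4, sliceThickness = 6,
                        orientation = c("axial", "coronal"),
                        leftSemiaxes = c(30, 22, 52),
                        rightSemiaxes = c(28, 20, 48),
                        leftCenter = c(44, 0, 0),
                        rightCenter = c(-44, 0, 0),
                        nCysts = 3L, cystRadiusRange = c(4, 10),
                        noiseSd = 8,
                        backgroundIntensity = 30, kidneyIntensity = 120,
                        cystIntensity = 220,
                        seed = 1L, subjectId = "phantom") {
  orientation <- match.arg(orientation)
  stopifnot(nSlices >= 1, nRows >= 1, nCols >= 1,
            pixelSpacing > 0, sliceThickness > 0,
            all(leftSemiaxes > 0), all(rightSemiaxes > 0),
            nCysts >= 0, cystRadiusRange[1] <= cystRadiusRange[2],
            noiseSd >= 0)
  ints <- c(backgroundIntensity, kidneyIntensity, cystIntensity)
  if (any(ints < 0) || any(ints > 255))
    stop("spec error: intensities must lie in [0, 255]")
  structure(list(nSlices = as.integer(nSlices), nRows = as.integer(nRows),
                 nCols = as.integer(nCols), pixelSpacing = pixelSpacing,
                 sliceThickness = sliceThickness, orientation = orientation,
                 leftSemiaxes = leftSemiaxes, rightSemiaxes = rightSemiaxes,
                 leftCenter = leftCenter, rightCenter = rightCenter,
                 nCysts = as.integer(nCysts), cystRadiusRange = cystRadiusRange,
                 noiseSd = noiseSd, backgroundIntensity = backgroundIntensity,
                 kidneyIntensity = kidneyIntensity, cystIntensity = cystIntensity,
                 seed = as.integer(seed), subjectId = subjectId),
            class = "PhantomSpec")
}

# World coordinates of the grid, centered on the field of view.
# Axial slices are (row ~ y, col ~ x) stacked along z; coronal slices
# are (row ~ z, col ~ x) stacked along y.
.phantomFrame <- function(spec) {
  xs <- ((seq_len(spec$nCols)) - 0.5 - spec$nCols / 2) * spec$pixelSpacing
  rowc <- ((seq_len(spec$nRows)) - 0.5 - spec$nRows / 2) * spec$pixelSpacing
  zs <- ((seq_len(spec$nSlices)) - 0.5 - spec$nSlices / 2) * spec$sliceThickness
  if (spec$orientation == "axial")
    list(col = xs, row = rowc, slice = zs, axes = c("x", "y", "z"))
  else
    list(col = xs, row = rowc, slice = zs, axes = c("x", "z", "y"))
}

# World (x, y, z) of every pixel center of slice k, in grid layout.
.sliceCoords <- function(fr, spec, k) {
  nr <- spec$nRows; nc <- spec$nCols
  colW <- matrix(fr$col, nr, nc, byrow = TRUE)
  rowW <- matrix(fr$row, nr, nc)
  s <- fr$slice[k]
  if (spec$orientation == "axial")
    list(x = colW, y = rowW, z = matrix(s, nr, nc))
  else
    list(x = colW, y = matrix(s, nr, nc), z = rowW)
}

.ellipsoidMask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

# Uniform draw inside the unit ball (rejection), scaled to the ellipsoid.
.drawCystCenters <- function(n, center, semi, margin = 0.7) {
  out <- matrix(0, n, 3)
  i <- 0
  while (i < n) {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) <= 1) {
      i <- i + 1
      out[i, ] <- center + margin * u * semi
    }
  }
  out
}

#' Generate one synthetic phantom case
#'
#' Renders each slice as the cross-section of the two kidney ellipsoids
#' at that slice position, adds bright spherical cysts clipped to the
#' kidney interiors, then additive Gaussian noise clipped to [0, 255]
#' and rounded to integer intensities. Truth masks are the exact
#' noise-free ellipsoid cross-sections (cysts count as kidney). The
#' result is deterministic given the spec (including its seed).
#'
#' @param spec a [phantomSpec()].
#' @return a \linkS4class{PhantomCase}.
#' @examples
#' case <- generatePhantom(phantomSpec(seed = 7))
#' totalMl(trueVolumes(case))
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  fr <- .phantomFrame(spec)
  nr <- spec$nRows; nc <- spec$nCols; ns <- spec$nSlices

  .withSeed(spec$seed, {
    cystsL <- if (spec$nCysts > 0)
      .drawCystCenters(spec$nCysts, spec$leftCenter, spec$leftSemiaxes) else NULL
    cystsR <- if (spec$nCysts > 0)
      .drawCystCenters(spec$nCysts, spec$rightCenter, spec$rightSemiaxes) else NULL
    radii <- if (spec$nCysts > 0)
      stats::runif(2 * spec$nCysts, spec$cystRadiusRange[1],
                   spec$cystRadiusRange[2]) else numeric(0)
    cysts <- rbind(cystsL, cystsR)

    slicesOut <- vector("list", ns)
    leftM <- vector("list", ns); rightM <- vector("list", ns)
    for (k in seq_len(ns)) {
      co <- .sliceCoords(fr, spec, k)
      ml <- .ellipsoidMask(co, spec$leftCenter, spec$leftSemiaxes)
      mr <- .ellipsoidMask(co, spec$rightCenter, spec$rightSemiaxes)
      if (any(ml & mr))
        stop("spec error: kidneys overlap at the stated centers/semiaxes")
      img <- matrix(spec$backgroundIntensity, nr, nc)
      img[ml | mr] <- spec$kidneyIntensity
      if (spec$nCysts > 0) {
        for (ci in seq_len(nrow(cysts))) {
          inCyst <- (co$x - cysts[ci, 1])^2 + (co$y - cysts[ci, 2])^2 <=
            radii[ci]^2 - (co$z - cysts[ci, 3])^2
          inCyst <- inCyst & (ml | mr)  # cysts only inside kidneys
          img[inCyst] <- spec$cystIntensity
        }
      }
      if (spec$noiseSd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noiseSd), nr, nc)
      slicesOut[[k]] <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), nr, nc)
      leftM[[k]] <- ml * 1
      rightM[[k]] <- mr * 1
    }
    geom <- seriesGeometry(spec$pixelSpacing, spec$pixelSpacing,
                           spec$sliceThickness, spec$sliceThickness,
                           nr, nc, spec$orientation)
    stack <- sliceStack(slicesOut, geom, subjectId = spec$subjectId,
                        slicePositions = fr$slice)
    truth <- new("LateralizedMaskStack", left = leftM, right = rightM,
                 geometry = geom)
    trueV <- totalKidneyVolume(truth, subjectId = spec$subjectId)
    ellML <- function(s) 4 / 3 * pi * prod(s) / 1000
    analytic <- kidneyVolumes(ellML(spec$leftSemiaxes), ellML(spec$rightSemiaxes),
                              method = "planimetric", subjectId = spec$subjectId)
    new("PhantomCase", stack = stack, truth = truth, trueVolumes = trueV,
        analyticVolumes = analytic)
  })
}

#' Generate a cohort of phantom cases
#'
#' Per-case geometry is jittered around the base spec (semiaxes
#' +/- 15%, lateral centers +/- 5 mm) so cases differ in kidney size
#' and position as well as in noise and cysts.
#'
#' @param n number of cases.
#' @param baseSpec the shared [phantomSpec()].
#' @param seed cohort seed.
#' @return list of \linkS4class{PhantomCase}.
#' @export
makePhantomCohort <- function(n, baseSpec = phantomSpec(), seed = 1L) {
  jit <- .withSeed(seed, list(
    scl = matrix(stats::runif(6 * n, 0.85, 1.15), n, 6),
    dx = matrix(stats::runif(2 * n, -5, 5), n, 2),
    seeds = sample.int(2^30, n)))
  lapply(seq_len(n), function(i) {
    sp <- baseSpec
    sp$leftSemiaxes <- baseSpec$leftSemiaxes * jit$scl[i, 1:3]
    sp$rightSemiaxes <- baseSpec$rightSemiaxes * jit$scl[i, 4:6]
    sp$leftCenter <- baseSpec$leftCenter + c(jit$dx[i, 1], 0, 0)
    sp$rightCenter <- baseSpec$rightCenter + c(jit$dx[i, 2], 0, 0)
    sp$seed <- jit$seeds[i]
    sp$subjectId <- sprintf("%s%02d", baseSpec$subjectId, i)
    generatePhantom(sp)
  })
}

# Trace mask boundaries into polygon vertex chains (x = col, y = row,
# 0-based pixel-center coordinates).
.maskToPolygons <- function(mask, label) {
  if (sum(mask) == 0) return(list())
  cl <- grDevices::contourLines(x = 0:(nrow(mask) - 1), y = 0:(ncol(mask) - 1),
                                z = mask, levels = 0.5)
  out <- list()
  for (cc in cl) {
    if (length(cc$x) < 3) next
    verts <- cbind(cc$y, cc$x)  # contour x follows rows, y follows cols
    out[[length(out) + 1L]] <- polygonAnnotation(label, verts)
  }
  out
}

#' Export a phantom case to disk
#'
#' Writes the DICOM series (subdirectory \code{dicom/}), one
#' Labelme-style JSON per kidney-bearing slice (polygons approximating
#' the truth masks), and \code{ground_truth.csv} with per-side volumes.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param directory output directory.
#' @return invisibly, a manifest list with \code{dicomFiles},
#'   \code{annotationFiles}, \code{groundTruthCsv}.
#' @export
exportPhantomCase <- function(case, directory) {
  if (!is(case, "PhantomCase")) stop("input error: 'case' must be a PhantomCase")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("I/O error: cannot create ", directory)
  stack <- case@stack
  man <- writeDicomSeries(stack, file.path(directory, "dicom"))
  annDir <- file.path(directory, "annotations")
  dir.create(annDir, showWarnings = FALSE)
  g <- stack@geometry
  annFiles <- character(0)
  for (i in seq_len(length(stack@slices))) {
    anns <- c(.maskToPolygons(case@truth@left[[i]], "left_kidney"),
              .maskToPolygons(case@truth@right[[i]], "right_kidney"))
    if (length(anns) == 0) next
    f <- file.path(annDir, sprintf("IMG%04d.json", i))
    writeLabelme(anns, c(g@nRows, g@nCols), f,
                 imagePath = sprintf("IMG%04d.dcm", i))
    annFiles <- c(annFiles, f)
  }
  gtCsv <- file.path(directory, "ground_truth.csv")
  utils::write.csv(data.frame(subject_id = stack@subjectId,
                              left_ml = case@trueVolumes@leftMl,
                              right_ml = case@trueVolumes@rightMl,
                              total_ml = case@trueVolumes@totalMl),
                   gtCsv, row.names = FALSE)
  invisible(list(dicomFiles = man$file, annotationFiles = annFiles,
                 groundTruthCsv = gtCsv))
}
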