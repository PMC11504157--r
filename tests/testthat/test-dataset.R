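test_that("polygon rasterisation follows the pixel-center rule", {
  # empty annotation list
  expect_true(all(polygonsToMask(list(), c(16, 16)) == 0))

  # axis-aligned square spanning centers (10,10)-(19,19): exactly 100 px
  rect <- polygonAnnotation("left_kidney",
                            cbind(c(10, 19, 19, 10), c(10, 10, 19, 19)))
  m <- polygonsToMask(list(rect), c(64, 64))
  expect_equal(sum(m), 100)
  expect_equal(m[11, 11], 1)  # (row 10, col 10) 0-based
  expect_equal(m[10, 11], 0)

  expect_error(polygonAnnotation("left_kidney", cbind(c(1, 2), c(1, 2))),
               "3 vertices")
  expect_error(polygonAnnotation("spleen", cbind(c(1, 2, 3), c(1, 2, 3))),
               "label")
})

test_that("rasterisation agrees with a brute-force point-in-polygon oracle", {
  set.seed(21)
  for (rep in 1:5) {
    tri <- cbind(runif(3, 1, 30), runif(3, 1, 30))
    ann <- polygonAnnotation("right_kidney", tri)
    got <- polygonsToMask(list(ann), c(32, 32))
    ref <- oracleRasterize(tri, c(32, 32))
    expect_identical(got, ref)
  }
})

test_that("rasterised area approaches the shoelace polygon area", {
  # 100x100-px rectangle: relative error below 2%
  poly <- cbind(c(10.3, 110.3, 110.3, 10.3), c(8.7, 8.7, 108.7, 108.7))
  ann <- polygonAnnotation("left_kidney", poly)
  m <- polygonsToMask(list(ann), c(128, 128))
  shoelace <- 100 * 100
  expect_lt(abs(sum(m) - shoelace) / shoelace, 0.02)
})

test_that("train/validation split is exact, deterministic and a partition", {
  s <- splitTrainVal(seq_len(1483), 0.8, seed = 1)
  expect_equal(length(s$train), 1186)
  expect_equal(length(s$validation), 297)

  s10 <- splitTrainVal(seq_len(10), 0.8, seed = 2)
  expect_equal(lengths(s10[c("train", "validation")]), c(train = 8, validation = 2))

  expect_identical(splitTrainVal(1:50, 0.8, seed = 7),
                   splitTrainVal(1:50, 0.8, seed = 7))
  expect_false(identical(splitTrainVal(1:50, 0.8, seed = 7)$trainIdx,
                         splitTrainVal(1:50, 0.8, seed = 8)$trainIdx))

  set.seed(30)
  for (rep in 1:10) {
    n <- sample(2:200, 1); fr <- runif(1, 0.2, 0.9)
    sp <- splitTrainVal(seq_len(n), fr, seed = rep)
    expect_equal(length(sp$train), floor(n * fr))
    expect_setequal(c(sp$trainIdx, sp$validationIdx), seq_len(n))
    expect_length(intersect(sp$trainIdx, sp$validationIdx), 0)
  }
  expect_error(splitTrainVal(list(), 0.8, 1), "input error")
})

test_that("patient-wise split never leaks a subject across sets", {
  subj <- rep(sprintf("P%02d", 1:10), each = 7)
  sp <- splitTrainVal(seq_along(subj), 0.8, seed = 3, by = "patient",
                      subjectIds = subj)
  expect_length(intersect(unique(subj[sp$trainIdx]),
                          unique(subj[sp$validationIdx])), 0)
  expect_equal(length(unique(subj[sp$trainIdx])), 8)
})

test_that("augmentation with zero magnitudes is the identity", {
  set.seed(40)
  pair <- list(image = matrix(runif(64 * 64), 64, 64),
               mask = randomMask(64, 64, 0.2))
  p0 <- augmentationParams(0, 0, 0)
  expect_identical(augmentPair(pair, p0), pair)
})

test_that("a 90-degree rotation moves an impulse to the predicted pixel", {
  img <- matrix(0, 41, 41); img[11, 21] <- 1  # 10 px above center (0-based 10,20)
  pair <- list(image = img, mask = img)
  out <- augmentPair(pair, augmentationParams(),
                     draw = list(rot = 90, shiftR = 0, shiftC = 0, zoom = 1,
                                 flipH = FALSE, flipV = FALSE))
  # rotating the grid by +90 deg about the center (20,20) maps the
  # impulse from (r,c) = (10,20) to one of the two axes positions at
  # distance 10; locate the mass and check it
  peak <- which(out$mask == 1, arr.ind = TRUE)
  expect_equal(nrow(peak), 1)
  d <- sqrt((peak[1, 1] - 21)^2 + (peak[1, 2] - 21)^2)
  expect_lt(abs(d - 10), 1.01)                       # radius preserved
  expect_true(abs(peak[1, 1] - 21) <= 1.01 | abs(peak[1, 2] - 21) <= 1.01)
  expect_false(all(abs(peak[1, ] - c(11, 21)) <= 1)) # actually moved
})

test_that("augmentation preserves shapes, ranges and mask binarity", {
  set.seed(41)
  pair <- list(image = matrix(runif(48 * 48), 48, 48),
               mask = randomMask(48, 48, 0.3))
  pars <- augmentationParams(5, 0.1, 0.1)
  for (rep in 1:10) {
    out <- augmentPair(pair, pars)
    expect_equal(dim(out$image), dim(pair$image))
    expect_equal(dim(out$mask), dim(pair$mask))
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("Labelme files round trip through write and read", {
  anns <- list(
    polygonAnnotation("left_kidney", cbind(c(40, 50, 45), c(10, 12, 20))),
    polygonAnnotation("right_kidney", cbind(c(10, 20, 15, 8), c(10, 12, 20, 18))))
  f <- file.path(tempdir(), "ann.json")
  writeLabelme(anns, c(64, 64), f, imagePath = "IMG0001.dcm")
  lm <- readLabelme(f)
  expect_equal(lm$shape, c(64L, 64L))
  expect_equal(vapply(lm$annotations, function(a) a$label, character(1)),
               c("left_kidney", "right_kidney"))
  expect_equal(lm$annotations[[1]]$vertices, anns[[1]]$vertices,
               ignore_attr = TRUE)
})
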