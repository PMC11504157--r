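test_that("binarisation follows the 128 / 0.5 cut consistently", {
  expect_equal(binarizeMask(matrix(127, 1, 1)), matrix(0, 1, 1))
  expect_equal(binarizeMask(matrix(128, 1, 1)), matrix(1, 1, 1))
  expect_true(all(binarizeMask(matrix(0, 4, 4)) == 0))

  set.seed(50)
  p <- matrix(runif(100), 10, 10)
  expect_identical(binarizeMask(p), binarizeMask(p * 255))
  expect_identical(binarizeMask(binarizeMask(p)), binarizeMask(p))
  expect_error(binarizeMask(matrix(-1, 2, 2)), "domain error")
  expect_error(binarizeMask(matrix(300, 2, 2)), "domain error")
})

test_that("hole filling matches a border flood-fill reference", {
  # solid disk untouched
  xy <- expand.grid(r = 1:21, c = 1:21)
  disk <- matrix(as.numeric((xy$r - 11)^2 + (xy$c - 11)^2 <= 49), 21, 21)
  expect_identical(fillHoles(disk), disk)

  # 1-px ring becomes a filled disk
  ring <- matrix(0, 9, 9); ring[3:7, 3] <- 1; ring[3:7, 7] <- 1
  ring[3, 3:7] <- 1; ring[7, 3:7] <- 1
  filled <- fillHoles(ring)
  expect_equal(sum(filled), 25)
  expect_true(all(filled[3:7, 3:7] == 1))

  set.seed(51)
  for (rep in 1:200) {
    m <- randomMask(32, 32, runif(1, 0.2, 0.6))
    f <- fillHoles(m)
    expect_identical(f, oracleFillHoles(m))
    expect_true(all(f >= m))            # foreground never removed
    expect_identical(fillHoles(f), f)   # idempotent
  }
})

test_that("despeckle matches brute-force component-size filtering", {
  blob <- matrix(0, 10, 10); blob[3:6, 3:6] <- 1
  expect_identical(despeckle(blob, 16), blob)

  dots <- matrix(0, 8, 8); dots[cbind(c(1, 4, 7), c(1, 4, 7))] <- 1
  expect_true(all(despeckle(dots, 2) == 0))

  set.seed(52)
  for (rep in 1:100) {
    m <- randomMask(32, 32, runif(1, 0.15, 0.5))
    k <- sample(2:12, 1)
    d <- despeckle(m, k)
    expect_identical(d, oracleDespeckle(m, k))
    expect_true(all(d <= m))            # never adds foreground
    expect_identical(despeckle(d, k), d)
  }
})

test_that("filling before despeckling preserves ring-shaped sections", {
  ring <- matrix(0, 9, 9); ring[3:7, 3] <- 1; ring[3:7, 7] <- 1
  ring[3, 3:7] <- 1; ring[7, 3:7] <- 1   # 16 px perimeter, 25 px filled
  expect_equal(sum(despeckle(fillHoles(ring), 20)), 25)
  expect_equal(sum(fillHoles(despeckle(ring, 20))), 0)
})

test_that("left/right separation assigns components by centroid", {
  g <- seriesGeometry(1, 1, 5, 5, 20, 40, "axial")
  m <- matrix(0, 20, 40)
  m[8:12, 8:12] <- 1    # image-left -> patient-right
  m[8:12, 28:32] <- 1   # image-right -> patient-left
  lat <- splitLeftRight(list(m), g)
  expect_equal(sum(leftMasks(lat)[[1]][, 28:32]), 25)
  expect_equal(sum(leftMasks(lat)[[1]]), 25)
  expect_equal(sum(rightMasks(lat)[[1]][, 8:12]), 25)

  # empty slice allowed
  lat0 <- splitLeftRight(list(matrix(0, 20, 40)), g)
  expect_equal(sum(leftMasks(lat0)[[1]]) + sum(rightMasks(lat0)[[1]]), 0)

  # centroid exactly on the midline -> patient-left by the tie rule
  g2 <- seriesGeometry(1, 1, 5, 5, 11, 11, "axial")
  mid <- matrix(0, 11, 11); mid[4:8, 6] <- 1  # centroid col 5 (0-based) = midline
  latm <- splitLeftRight(list(mid), g2)
  expect_equal(sum(leftMasks(latm)[[1]]), 5)
  expect_equal(sum(rightMasks(latm)[[1]]), 0)
})

test_that("the split partitions the cleaned mask", {
  set.seed(53)
  g <- seriesGeometry(1, 1, 5, 5, 32, 32, "axial")
  masks <- lapply(1:5, function(i) despeckle(fillHoles(randomMask(32, 32, 0.35)), 4))
  lat <- suppressWarnings(splitLeftRight(masks, g))
  for (i in 1:5) {
    L <- leftMasks(lat)[[i]]; R <- rightMasks(lat)[[i]]
    expect_true(all(L * R == 0))
    expect_identical(pmax(L, R), masks[[i]])
  }
})

test_that("the full inpainting pipeline handles probability input", {
  g <- seriesGeometry(1, 1, 5, 5, 24, 24, "axial")
  p <- matrix(0.05, 24, 24)
  p[6:18, 4:10] <- 0.9; p[10:12, 6:8] <- 0.2   # blob with a hole
  p[2, 20] <- 0.95                             # speck
  lat <- postprocessStack(list(p), g, minSizePx = 5)
  m <- pmax(leftMasks(lat)[[1]], rightMasks(lat)[[1]])
  expect_equal(sum(m), 13 * 7)  # hole filled, speck removed
})
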