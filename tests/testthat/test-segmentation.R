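test_that("the network honours its shape and range contracts", {
  m <- buildUnet(unetConfig(depth = 2, baseFilters = 4, inputSize = 32), seed = 1)
  set.seed(70)
  p <- tkvseg:::.unetForward(m, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))

  # constant input -> constant output (translation-invariant network)
  pc <- tkvseg:::.unetForward(m, matrix(0, 32, 32))
  expect_lt(diff(range(pc)), 1e-12)

  expect_error(unetConfig(depth = 4, inputSize = 8), "config error")
})

test_that("the parameter count matches the closed form for depth 1, base 4", {
  m <- buildUnet(unetConfig(depth = 1, baseFilters = 4, inputSize = 16), seed = 1)
  # enc: (9*1*4+4) + (9*4*4+4); bottleneck: (9*4*8+8) + (9*8*8+8);
  # dec: up (9*8*4+4) + (9*8*4+4) + (9*4*4+4); head: 4+1
  expected <- 40 + 148 + 296 + 584 + 292 + 292 + 148 + 5
  expect_equal(countParams(m), expected)
})

test_that("the Dice loss reproduces forced counts and the DSC identity", {
  t4 <- matrix(0, 4, 4); t4[1:2, 1:2] <- 1
  expect_lt(diceLoss(t4, t4), 1e-6)
  dis <- matrix(0, 4, 4); dis[3:4, 3:4] <- 1
  expect_gt(diceLoss(dis, t4), 1 - 1e-6)
  p6 <- t4; p6[3, 1:2] <- 1
  expect_equal(diceLoss(p6, t4), 0.2, tolerance = 1e-6)
  expect_error(diceLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "domain error")

  set.seed(71)
  for (rep in 1:10) {
    p <- randomMask(8, 8, 0.4); t <- randomMask(8, 8, 0.4)
    expect_equal(diceLoss(p, t, eps = 1e-12), 1 - dsc(confusionCounts(p, t)),
                 tolerance = 1e-9)
  }
})

test_that("the learning-rate schedule ramps then decays continuously", {
  sch <- list(warmupSteps = 100, peakLr = 1e-3, decayRate = 0.9,
              decaySteps = 50)
  expect_equal(lrAtStep(0, sch), 0)
  expect_equal(lrAtStep(100, sch), 1e-3)
  expect_equal(lrAtStep(150, sch), 1e-3 * 0.9)
  expect_equal(lrAtStep(50, sch), 5e-4)
  # continuity at the junction
  expect_lt(abs(lrAtStep(99.999, sch) - lrAtStep(100, sch)), 1e-7)
})

test_that("early stopping fires after patience epochs without improvement", {
  set.seed(72)
  pairs <- lapply(1:4, function(i)
    list(image = matrix(runif(16 * 16), 16, 16), mask = randomMask(16, 16, 0.3)))
  model <- buildUnet(unetConfig(depth = 1, baseFilters = 2, inputSize = 16),
                     seed = 1)
  fit <- trainUnet(model, pairs[1:2], pairs[3:4],
                   trainConfig(batchSize = 2, maxEpochs = 50, patience = 1,
                               seed = 1),
                   augParams = NULL,
                   valMetricFn = function(model, valPairs) 0.5)
  expect_equal(fit$stoppedEpoch, 2L)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$bestEpoch, 1L)
  expect_lte(fit$bestEpoch, fit$stoppedEpoch)
  expect_error(trainUnet(model, list(), pairs, trainConfig()), "input error")
})

test_that("a few epochs on an easy blob task reduce the loss", {
  set.seed(73)
  mkPair <- function(seed) {
    set.seed(seed)
    m <- matrix(0, 32, 32)
    r <- sample(8:20, 1); c <- sample(8:20, 1)
    m[r:(r + 7), c:(c + 7)] <- 1
    img <- 0.15 + 0.5 * m + matrix(rnorm(32 * 32, 0, 0.05), 32, 32)
    list(image = pmin(pmax(img, 0), 1), mask = m)
  }
  pairs <- lapply(1:8, mkPair)
  model <- buildUnet(unetConfig(depth = 1, baseFilters = 4, inputSize = 32),
                     seed = 3)
  fit <- trainUnet(model, pairs[1:6], pairs[7:8],
                   trainConfig(batchSize = 6, maxEpochs = 10, patience = 10,
                               warmupEpochs = 2, peakLr = 2e-3, seed = 3),
                   augParams = NULL)
  expect_lt(fit$history$loss[10], fit$history$loss[1])
  expect_equal(nrow(fit$history), fit$stoppedEpoch)
})

test_that("prediction maps probabilities back to the native grid", {
  g <- seriesGeometry(1, 1, 5, 5, 48, 40, "axial")
  set.seed(74)
  sl <- lapply(1:3, function(i) matrix(sample(0:255, 48 * 40, TRUE), 48, 40))
  st <- sliceStack(sl, g, "predA")
  m <- buildUnet(unetConfig(depth = 2, baseFilters = 4, inputSize = 32), seed = 2)
  pr <- predictStack(m, st)
  expect_length(pr, 3)
  for (p in pr) {
    expect_equal(dim(p), c(48L, 40L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("checkpoints round trip through save and load", {
  m <- buildUnet(unetConfig(depth = 1, baseFilters = 2, inputSize = 16), seed = 5)
  f <- file.path(tempdir(), "ckpt.rds")
  saveUnet(m, f, trainConfig(seed = 5))
  m2 <- loadUnet(f)
  expect_identical(m2$params, m$params)
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(side$nParams, countParams(m))
  expect_equal(side$unetConfig$depth, 1)
})
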