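test_that("confusion counts match exhaustive per-voxel comparison", {
  m <- randomMask(8, 8, 0.4)
  cc <- confusionCounts(m, m)
  expect_equal(cc, list(tp = sum(m), fp = 0, fn = 0))
  cc2 <- confusionCounts(matrix(0, 8, 8), m)
  expect_equal(cc2$fn, sum(m))

  set.seed(60)
  for (rep in 1:20) {
    p <- randomMask(10, 12, runif(1, 0.2, 0.7))
    t <- randomMask(10, 12, runif(1, 0.2, 0.7))
    got <- confusionCounts(p, t)
    ref <- list(tp = 0, fp = 0, fn = 0)
    for (i in 1:10) for (j in 1:12) {
      if (p[i, j] == 1 && t[i, j] == 1) ref$tp <- ref$tp + 1
      if (p[i, j] == 1 && t[i, j] == 0) ref$fp <- ref$fp + 1
      if (p[i, j] == 0 && t[i, j] == 1) ref$fn <- ref$fn + 1
    }
    expect_equal(got, ref)
  }
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("DSC and Jaccard formulas and their identity hold", {
  expect_equal(dsc(list(tp = 2, fp = 1, fn = 1)), 2 / 3)
  expect_equal(jaccard(list(tp = 2, fp = 1, fn = 1)), 0.5)
  expect_equal(dsc(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_equal(dsc(list(tp = 0, fp = 3, fn = 4)), 0)
  expect_equal(jaccard(list(tp = 0, fp = 0, fn = 0)), 1)  # empty vs empty

  set.seed(61)
  for (rep in 1:50) {
    c0 <- list(tp = sample(0:500, 1), fp = sample(0:300, 1), fn = sample(0:300, 1))
    if (c0$tp + c0$fp + c0$fn == 0) next
    D <- dsc(c0); J <- jaccard(c0)
    expect_lt(abs(J - D / (2 - D)), 1e-12)
  }
})

test_that("agreement rows reproduce hand-computed differences", {
  at <- agreementTable(2992.23, 3004.72, "case1")
  expect_equal(at$rows$diff_ml, 12.49)
  expect_equal(round(at$rows$diff_pct, 2), 0.42)

  same <- agreementTable(c(100, 200, 300), c(100, 200, 300))
  expect_true(all(same$rows$diff_ml == 0))
  expect_true(all(same$summary[same$summary$statistic == "sd",
                               c("diff_ml", "diff_pct")] == 0))
  expect_error(agreementTable(c(0, 10), c(1, 2)), "domain error")
})

test_that("agreement summary uses the sample (n-1) standard deviation", {
  tr <- c(100, 200, 300, 400); pr <- c(110, 190, 330, 380)
  at <- agreementTable(tr, pr)
  d <- abs(pr - tr)
  manualSd <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  expect_equal(at$summary$diff_ml[at$summary$statistic == "sd"], manualSd)
})

test_that("Bland-Altman bias and limits follow the stated conventions", {
  ident <- blandAltman(c(100, 200, 300), c(100, 200, 300))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loaLower, ident$loaUpper), c(0, 0))

  # +x% and -x% around the pairwise mean cancel
  tr <- c(100, 100); pr <- c(100 * 1.1 / 0.9, 100 * 0.9 / 1.1)
  sym <- blandAltman(tr, pr, denominator = "pairwise_mean")
  expect_lt(abs(sym$bias), 1e-10)

  # independent recomputation, every denominator convention
  set.seed(62)
  tr <- runif(8, 500, 3000); pr <- tr * runif(8, 0.8, 1.2)
  for (den in c("pairwise_mean", "truth", "pred")) {
    ba <- blandAltman(tr, pr, denominator = den)
    d <- switch(den, pairwise_mean = (tr + pr) / 2, truth = tr, pred = pr)
    pct <- 100 * (pr - tr) / d
    expect_equal(ba$bias, mean(pct))
    expect_equal(ba$loaUpper - ba$loaLower, 2 * 1.96 * sd(pct))
    expect_equal(ba$diffPct, pct)
  }
  ba <- blandAltman(tr, pr)
  expect_equal(rownames(ba$allConventions),
               c("pairwise_mean", "truth", "pred"))
  expect_error(blandAltman(100, 100), "input error")
})

test_that("group comparison returns sensible two-sided p-values", {
  expect_equal(compareGroups(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)

  set.seed(63)
  a <- rnorm(10, 0, 0.1); b <- rnorm(10, 5, 0.1)
  expect_lt(compareGroups(a, b), 0.01)

  # the two bundled reference cohorts do not differ significantly
  ax <- read.csv(system.file("extdata", "agreement_axial.csv", package = "tkvseg"))
  co <- read.csv(system.file("extdata", "agreement_coronal.csv", package = "tkvseg"))
  expect_gt(compareGroups(ax$ground_truth_ml, co$ground_truth_ml), 0.05)
  expect_error(compareGroups(1, c(1, 2)), "input error")
})
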