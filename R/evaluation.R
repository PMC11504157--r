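# Segmentation accuracy (DSC, Jaccard), volume agreement tables and
# Bland-Altman analysis.

#' Voxelwise confusion counts between predicted and reference masks
#'
#' Tallies TP/FP/FN voxels pooled over all slices of one subject (true
#' negatives are not needed for overlap metrics).
#'
#' @param pred,truth aligned lists of binary matrices (or single
#'   matrices).
#' @return list with \code{tp}, \code{fp}, \code{fn}.
#' @export
confusionCounts <- function(pred, truth) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(pred) != length(truth))
    stop("shape error: stacks have different lengths")
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[[i]]; t <- truth[[i]]
    if (!identical(dim(p), dim(t)))
      stop("shape error: slice dimensions differ")
    tp <- tp + sum(p == 1 & t == 1)
    fp <- fp + sum(p == 1 & t == 0)
    fn <- fn + sum(p == 0 & t == 1)
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Dice similarity coefficient
#'
#' DSC = 2TP / (2TP + FP + FN); defined as 1 when both masks are empty.
#'
#' @param counts a [confusionCounts()] list.
#' @return DSC in [0, 1].
#' @export
dsc <- function(counts) {
  d <- 2 * counts$tp + counts$fp + counts$fn
  if (d == 0) return(1)
  2 * counts$tp / d
}

#' Jaccard coefficient
#'
#' Jaccard = TP / (TP + FP + FN); defined as 1 when both masks are
#' empty. Satisfies J = D / (2 - D).
#'
#' @param counts a [confusionCounts()] list.
#' @return Jaccard index in [0, 1].
#' @export
jaccard <- function(counts) {
  d <- counts$tp + counts$fp + counts$fn
  if (d == 0) return(1)
  counts$tp / d
}

#' Per-case volume agreement table with summary
#'
#' For each case computes the absolute difference |predicted - truth|
#' (mL) and the percent difference 100 * diff / truth, then summarises
#' each column by its mean and sample standard deviation (n - 1
#' denominator).
#'
#' @param truthMl reference volumes (mL), strictly positive.
#' @param predMl predicted volumes (mL).
#' @param subjectIds case identifiers.
#' @return list with \code{rows} (data.frame: subject_id,
#'   ground_truth_ml, predicted_ml, diff_ml, diff_pct) and
#'   \code{summary} (data.frame of mean/sd per column, plus \code{n}).
#' @export
agreementTable <- function(truthMl, predMl, subjectIds = NULL) {
  if (length(truthMl) != length(predMl))
    stop("input error: truth and prediction lengths differ")
  if (any(truthMl <= 0))
    stop("domain error: ground-truth volumes must be > 0")
  if (is.null(subjectIds))
    subjectIds <- sprintf("case%02d", seq_along(truthMl))
  diffMl <- abs(predMl - truthMl)
  diffPct <- 100 * diffMl / truthMl
  rows <- data.frame(subject_id = subjectIds, ground_truth_ml = truthMl,
                     predicted_ml = predMl, diff_ml = diffMl,
                     diff_pct = diffPct, stringsAsFactors = FALSE)
  cols <- rows[, c("ground_truth_ml", "predicted_ml", "diff_ml", "diff_pct")]
  summary <- data.frame(
    statistic = c("mean", "sd"),
    ground_truth_ml = c(mean(cols$ground_truth_ml), stats::sd(cols$ground_truth_ml)),
    predicted_ml = c(mean(cols$predicted_ml), stats::sd(cols$predicted_ml)),
    diff_ml = c(mean(cols$diff_ml), stats::sd(cols$diff_ml)),
    diff_pct = c(mean(cols$diff_pct), stats::sd(cols$diff_pct)),
    stringsAsFactors = FALSE)
  list(rows = rows, summary = summary, n = length(truthMl))
}

#' Bland-Altman analysis of volume agreement
#'
#' Computes per-case signed percent differences under a stated
#' convention, the bias (mean) and the 95% limits of agreement
#' bias +/- 1.96 * SD. Because the percent-difference convention is a
#' recurring source of ambiguity, the result also carries the bias/LoA
#' under all three denominators.
#'
#' @param truthMl,predMl paired volumes (mL), n >= 2.
#' @param signConvention \code{"pred_minus_truth"} (default) or
#'   \code{"truth_minus_pred"}.
#' @param denominator \code{"pairwise_mean"} (default), \code{"truth"}
#'   or \code{"pred"}.
#' @return list with \code{diffPct}, \code{bias}, \code{loaLower},
#'   \code{loaUpper}, \code{meansMl}, the convention flags and
#'   \code{allConventions} (data.frame over the three denominators).
#' @export
blandAltman <- function(truthMl, predMl,
                        signConvention = c("pred_minus_truth", "truth_minus_pred"),
                        denominator = c("pairwise_mean", "truth", "pred")) {
  signConvention <- match.arg(signConvention)
  denominator <- match.arg(denominator)
  if (length(truthMl) != length(predMl) || length(truthMl) < 2)
    stop("input error: need >= 2 aligned pairs")
  num <- if (signConvention == "pred_minus_truth") predMl - truthMl else
    truthMl - predMl
  den <- function(which) switch(which,
    pairwise_mean = (truthMl + predMl) / 2,
    truth = truthMl, pred = predMl)
  one <- function(which) {
    d <- den(which)
    if (any(d == 0)) stop("domain error: zero denominator in percent difference")
    pct <- 100 * num / d
    c(bias = mean(pct), sd = stats::sd(pct),
      loaLower = mean(pct) - 1.96 * stats::sd(pct),
      loaUpper = mean(pct) + 1.96 * stats::sd(pct))
  }
  all3 <- t(vapply(c("pairwise_mean", "truth", "pred"), one, numeric(4)))
  sel <- one(denominator)
  list(diffPct = 100 * num / den(denominator),
       bias = unname(sel["bias"]),
       loaLower = unname(sel["loaLower"]), loaUpper = unname(sel["loaUpper"]),
       meansMl = (truthMl + predMl) / 2,
       signConvention = signConvention, denominator = denominator,
       allConventions = as.data.frame(all3))
}

#' Bland-Altman plot
#'
#' Mean volume vs signed percent difference with bias and limits of
#' agreement as horizontal lines.
#'
#' @param ba a [blandAltman()] result.
#' @param main plot title.
#' @return invisibly, \code{ba}.
#' @export
plotBlandAltman <- function(ba, main = "Bland-Altman agreement") {
  graphics::plot(ba$meansMl, ba$diffPct, pch = 19,
                 xlab = "Mean of reference and predicted TKV (mL)",
                 ylab = sprintf("Difference (%%, %s / %s)", ba$signConvention,
                                ba$denominator),
                 main = main,
                 ylim = range(c(ba$diffPct, ba$loaLower, ba$loaUpper)))
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loaLower, ba$loaUpper), lty = 2)
  invisible(ba)
}

#' Two-sample comparison p-value
#'
#' Two-sided two-sample test: Student's t-test when both samples pass a
#' Shapiro-Wilk normality check (or when \code{method = "t"}), otherwise
#' the Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param a,b numeric samples, n >= 2 each.
#' @param method \code{"auto"} (normality-gated, default), \code{"t"} or
#'   \code{"wilcoxon"}.
#' @param alpha normality-check level for \code{"auto"} (default 0.05).
#' @return two-sided p-value.
#' @export
compareGroups <- function(a, b, method = c("auto", "t", "wilcoxon"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    stop("input error: each group needs >= 2 observations")
  if (method == "auto") {
    normal <- function(x) {
      if (length(unique(x)) < 3) return(FALSE)
      stats::shapiro.test(x)$p.value > alpha
    }
    method <- if (normal(a) && normal(b)) "t" else "wilcoxon"
  }
  if (method == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
      stop("degenerate samples: zero variance in both groups")
    }
    stats::t.test(a, b)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
  }
}
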