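# Training loop: per-epoch fresh augmentation, Adam with warm-up
# exponential decay, early stopping on the validation Dice monitor.

.adamInit <- function(params) {
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

.adamStep <- function(params, grads, state, lr, cfg) {
  t <- state$t + 1
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state$m[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$dW
    s$vW <- b2 * s$vW + (1 - b2) * g$dW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$db
    s$vb <- b2 * s$vb + (1 - b2) * g$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state$m[[nm]] <- s
  }
  state$t <- t
  list(params = params, state = state)
}

# Mean slice-wise validation DSC at the 0.5 probability cut
# (empty-vs-empty slices score 1).
.validationDsc <- function(model, valPairs) {
  mean(vapply(valPairs, function(pr) {
    p <- (.unetForward(model, pr$image) >= 0.5) * 1
    dsc(confusionCounts(p, pr$mask))
  }, numeric(1)))
}

#' Train the U-Net
#'
#' Minibatch Adam on the Dice loss with a fresh random augmentation of
#' every training pair at every epoch. The validation Dice (computed on
#' un-augmented pairs at the 0.5 threshold) is monitored for early
#' stopping with best-weight restoration. The run is fully seeded via
#' \code{trainCfg$seed}.
#'
#' @param model a [buildUnet()] model (its weights are the starting
#'   point).
#' @param trainPairs,valPairs non-empty lists of \code{(image, mask)}
#'   pairs on the model grid (see [labeledPairs()]).
#' @param trainCfg a [trainConfig()].
#' @param augParams an [augmentationParams()]; \code{NULL} disables
#'   augmentation.
#' @param valMetricFn optional override of the validation monitor, a
#'   \code{function(model, valPairs)} returning a scalar (higher is
#'   better).
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best weights), \code{history}
#'   (data.frame epoch/loss/val_dsc/lr), \code{bestEpoch},
#'   \code{stoppedEpoch}, \code{bestValDsc}.
#' @export
trainUnet <- function(model, trainPairs, valPairs, trainCfg = trainConfig(),
                      augParams = augmentationParams(), valMetricFn = NULL,
                      verbose = FALSE) {
  if (length(trainPairs) == 0 || length(valPairs) == 0)
    stop("input error: train and validation sets must be non-empty")
  stopifnot(inherits(trainCfg, "TrainConfig"))
  n <- length(trainPairs)
  stepsPerEpoch <- max(1L, ceiling(n / trainCfg$batchSize))
  schedule <- list(warmupSteps = trainCfg$warmupEpochs * stepsPerEpoch,
                   peakLr = trainCfg$peakLr, decayRate = trainCfg$decayRate,
                   decaySteps = stepsPerEpoch)
  metric <- if (is.null(valMetricFn)) .validationDsc else valMetricFn

  .withSeed(trainCfg$seed, {
    state <- list(t = 0, m = .adamInit(model$params))
    bestParams <- model$params
    bestVal <- -Inf; bestEpoch <- 0L
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       val_dsc = numeric(0), lr = numeric(0))
    step <- 0L
    stoppedEpoch <- trainCfg$maxEpochs
    for (epoch in seq_len(trainCfg$maxEpochs)) {
      ord <- sample.int(n)
      epochLoss <- 0; nb <- 0
      for (bi in seq_len(stepsPerEpoch)) {
        idx <- ord[(((bi - 1) * trainCfg$batchSize) + 1):min(bi * trainCfg$batchSize, n)]
        lr <- lrAtStep(step, schedule)
        gradSum <- NULL; lossSum <- 0
        for (j in idx) {
          pr <- trainPairs[[j]]
          if (!is.null(augParams)) pr <- augmentPair(pr, augParams)
          fw <- .unetForward(model, pr$image, training = TRUE, withCache = TRUE)
          truth <- array(pr$mask, dim(fw$prob))
          lossSum <- lossSum + diceLoss(fw$prob, truth)
          g <- .unetBackward(model, fw$cache, .diceLossGrad(fw$prob, truth))
          if (is.null(gradSum)) gradSum <- g else
            for (nm in names(g)) {
              gradSum[[nm]]$dW <- gradSum[[nm]]$dW + g[[nm]]$dW
              gradSum[[nm]]$db <- gradSum[[nm]]$db + g[[nm]]$db
            }
        }
        for (nm in names(gradSum)) {
          gradSum[[nm]]$dW <- gradSum[[nm]]$dW / length(idx)
          gradSum[[nm]]$db <- gradSum[[nm]]$db / length(idx)
        }
        upd <- .adamStep(model$params, gradSum, state, lr, trainCfg)
        model$params <- upd$params; state <- upd$state
        step <- step + 1L
        epochLoss <- epochLoss + lossSum / length(idx); nb <- nb + 1
      }
      valDsc <- metric(model, valPairs)
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epochLoss / nb,
                                     val_dsc = valDsc,
                                     lr = lrAtStep(step - 1L, schedule)))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch,
                        epochLoss / nb, valDsc))
      if (valDsc > bestVal + trainCfg$minDelta) {
        bestVal <- valDsc; bestEpoch <- epoch
        bestParams <- model$params
      } else if (epoch - bestEpoch >= trainCfg$patience) {
        stoppedEpoch <- epoch
        break
      }
      stoppedEpoch <- epoch
    }
    model$params <- bestParams
    list(model = model, history = hist, bestEpoch = bestEpoch,
         stoppedEpoch = stoppedEpoch, bestValDsc = bestVal)
  })
}

#' Predict per-slice probability masks for a series
#'
#' Each slice is resampled to the model grid ([prepareForModel()]),
#' passed through the network, and the probability map is bilinearly
#' resampled back to the native \code{(nRows, nCols)} grid.
#'
#' @param model a trained [buildUnet()] model.
#' @param stack a \linkS4class{SliceStack}.
#' @return list of probability matrices on the native grid, one per
#'   slice, values in (0, 1).
#' @export
predictStack <- function(model, stack) {
  stopifnot(is(stack, "SliceStack"))
  g <- stack@geometry
  lapply(stack@slices, function(s) {
    x <- prepareForModel(s, model$cfg$inputSize)
    p <- .unetForward(model, x)
    .bilinearResample(p, g@nRows, g@nCols)
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file of the model handle plus a JSON sidecar
#' (\code{<path>.json}) describing the architecture and, optionally, the
#' training configuration.
#'
#' @param model a model handle.
#' @param path checkpoint path (e.g. \code{model.rds}).
#' @param trainCfg optional [trainConfig()] recorded in the sidecar.
#' @return invisibly, \code{path}.
#' @export
saveUnet <- function(model, path, trainCfg = NULL) {
  saveRDS(model, path)
  side <- list(unetConfig = unclass(model$cfg),
               nParams = countParams(model))
  if (!is.null(trainCfg)) side$trainConfig <- unclass(trainCfg)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveUnet
#' @export
loadUnet <- function(path) readRDS(path)
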