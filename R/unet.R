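# Modified 2D U-Net: padding-same convolutions, He initialisation, ReLU
# activations with a sigmoid head, dropout at the end of the contracting
# path, Dice loss, Adam with a warm-up exponential-decay learning-rate
# schedule. Implemented on BLAS matrix multiplications via im2col.

#' U-Net architecture configuration
#'
#' @param depth number of down-sampling stages (default 4).
#' @param baseFilters filters of the first encoder stage (default 32);
#'   doubled at each stage.
#' @param dropoutRate dropout at the end of the contracting path
#'   (default 0.2).
#' @param inputSize model grid side length (default 256); must be
#'   divisible by \code{2^depth}.
#' @return a \code{UNetConfig} (validated list). Padding is fixed to
#'   "same", hidden activations to ReLU, the head to sigmoid and weight
#'   initialisation to He.
#' @export
unetConfig <- function(depth = 4L, baseFilters = 32L, dropoutRate = 0.2,
                       inputSize = 256L) {
  stopifnot(depth >= 1, baseFilters >= 1, dropoutRate >= 0, dropoutRate < 1)
  if (inputSize %% (2^depth) != 0 || inputSize / 2^depth < 1)
    stop("config error: inputSize must be divisible by 2^depth with a ",
         "non-degenerate bottleneck")
  structure(list(depth = as.integer(depth), baseFilters = as.integer(baseFilters),
                 dropoutRate = dropoutRate, inputSize = as.integer(inputSize),
                 padding = "same", weightInit = "he",
                 hiddenActivation = "relu", finalActivation = "sigmoid"),
            class = "UNetConfig")
}

#' Training configuration
#'
#' @param batchSize minibatch size (default 10).
#' @param maxEpochs epoch cap (default 500).
#' @param warmupEpochs epochs of linear learning-rate ramp (default 5).
#' @param peakLr learning rate at the end of the ramp (default 1e-3).
#' @param decayRate per-epoch exponential decay after the ramp
#'   (default 0.9).
#' @param patience early-stopping patience in epochs on the validation
#'   Dice monitor (default 20).
#' @param minDelta minimum improvement to reset patience (default 1e-4).
#' @param beta1,beta2,epsilon Adam moment parameters (framework
#'   defaults).
#' @param seed integer seed for weight init, shuffling, augmentation and
#'   dropout.
#' @return a \code{TrainConfig} (validated list).
#' @export
trainConfig <- function(batchSize = 10L, maxEpochs = 500L, warmupEpochs = 5,
                        peakLr = 1e-3, decayRate = 0.9, patience = 20L,
                        minDelta = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, seed = 1L) {
  stopifnot(batchSize >= 1, maxEpochs >= 1, peakLr > 0, decayRate > 0,
            patience >= 1)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 warmupEpochs = warmupEpochs, peakLr = peakLr,
                 decayRate = decayRate, patience = as.integer(patience),
                 minDelta = minDelta, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given optimisation step
#'
#' Linear warm-up from \code{floorLr} to \code{peakLr} over
#' \code{warmupSteps}, then exponential decay
#' \code{peakLr * decayRate^((step - warmupSteps) / decaySteps)};
#' continuous at the junction.
#'
#' @param step step index, >= 0.
#' @param schedule list with \code{warmupSteps}, \code{peakLr},
#'   \code{decayRate}, \code{decaySteps} and optionally \code{floorLr}
#'   (default 0).
#' @return learning rate.
#' @examples
#' sch <- list(warmupSteps = 100, peakLr = 1e-3, decayRate = 0.9,
#'             decaySteps = 100)
#' lrAtStep(0, sch); lrAtStep(100, sch); lrAtStep(200, sch)
#' @export
lrAtStep <- function(step, schedule) {
  floorLr <- if (is.null(schedule$floorLr)) 0 else schedule$floorLr
  if (schedule$warmupSteps > 0 && step < schedule$warmupSteps)
    return(floorLr + (schedule$peakLr - floorLr) * step / schedule$warmupSteps)
  schedule$peakLr *
    schedule$decayRate^((step - schedule$warmupSteps) / schedule$decaySteps)
}

## ---- tensor ops (H x W x C arrays) ----------------------------------

# Memoised gather indices: column `col(ci, dj, di)` of the im2col matrix
# reads padded-array element (i + di - 1, j + dj - 1, ci) for output
# pixel (i, j).
.im2colIdxCache <- new.env(parent = emptyenv())

.im2colIdx <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  idx <- .im2colIdxCache[[key]]
  if (!is.null(idx)) return(idx)
  p <- (k - 1) %/% 2
  Hp <- H + 2 * p; Wp <- W + 2 * p
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  off <- expand.grid(di = seq_len(k), dj = seq_len(k), ci = seq_len(C))
  idx <- vapply(seq_len(nrow(off)), function(q) {
    as.integer((i + off$di[q] - 1) + (j + off$dj[q] - 2) * Hp +
                 (off$ci[q] - 1) * Hp * Wp)
  }, integer(H * W))
  dim(idx) <- NULL
  .im2colIdxCache[[key]] <- idx
  idx
}

.im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (k == 1) return(matrix(x, H * W, C))
  p <- (k - 1) %/% 2
  P <- array(0, c(H + 2 * p, W + 2 * p, C))
  P[p + seq_len(H), p + seq_len(W), ] <- x
  M <- P[.im2colIdx(H, W, C, k)]
  dim(M) <- c(H * W, k * k * C)
  M
}

.convForward <- function(x, layer) {
  d <- dim(x)
  M <- .im2col(x, layer$k)
  Y <- M %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  list(out = array(Y, c(d[1], d[2], ncol(layer$W))), M = M, inDim = d)
}

# Spatially flipped, channel-transposed weights: the gradient w.r.t. the
# conv input is itself a padding-same convolution of dY with these.
.flipWeights <- function(W, k) {
  cin <- nrow(W) / (k * k); cout <- ncol(W)
  perm <- as.vector(outer(seq_len(k), seq_len(k),
                          function(di, dj) (k - dj) * k + (k + 1 - di)))
  A <- array(W, c(k * k, cin, cout))[perm, , , drop = FALSE]
  matrix(aperm(A, c(1, 3, 2)), k * k * cout, cin)
}

.convBackward <- function(cache, layer, dOut) {
  d <- dim(dOut)
  dY <- matrix(dOut, d[1] * d[2], d[3])
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  if (layer$k == 1) {
    dX <- array(tcrossprod(dY, layer$W), cache$inDim)
  } else {
    dM <- .im2col(dOut, layer$k) %*% .flipWeights(layer$W, layer$k)
    dX <- array(dM, cache$inDim)
  }
  list(dW = dW, db = db, dX = dX)
}

.poolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  o <- seq(1, H, 2); e <- seq(2, H, 2)
  oc <- seq(1, W, 2); ec <- seq(2, W, 2)
  a1 <- x[o, oc, , drop = FALSE]; a2 <- x[e, oc, , drop = FALSE]
  a3 <- x[o, ec, , drop = FALSE]; a4 <- x[e, ec, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  arg <- array(4L, dim(m))
  arg[a3 == m] <- 3L; arg[a2 == m] <- 2L; arg[a1 == m] <- 1L
  list(out = m, arg = arg, inDim = d)
}

.poolBackward <- function(cache, dOut) {
  d <- cache$inDim
  dX <- array(0, d)
  o <- seq(1, d[1], 2); e <- seq(2, d[1], 2)
  oc <- seq(1, d[2], 2); ec <- seq(2, d[2], 2)
  sub <- list(list(o, oc), list(e, oc), list(o, ec), list(e, ec))
  for (k in 1:4) {
    tmp <- array(0, dim(dOut))
    sel <- cache$arg == k
    tmp[sel] <- dOut[sel]
    dX[sub[[k]][[1]], sub[[k]][[2]], ] <- tmp
  }
  dX
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.upsampleBackward <- function(dOut) {
  d <- dim(dOut)
  o <- seq(1, d[1], 2); e <- seq(2, d[1], 2)
  oc <- seq(1, d[2], 2); ec <- seq(2, d[2], 2)
  dOut[o, oc, , drop = FALSE] + dOut[e, oc, , drop = FALSE] +
    dOut[o, ec, , drop = FALSE] + dOut[e, ec, , drop = FALSE]
}

## ---- model ----------------------------------------------------------

.heConv <- function(k, cin, cout) {
  fanIn <- k * k * cin
  list(W = matrix(stats::rnorm(fanIn * cout, 0, sqrt(2 / fanIn)), fanIn, cout),
       b = numeric(cout), k = k)
}

#' Build the modified 2D U-Net
#'
#' Input \code{inputSize x inputSize x 1}, sigmoid output of the same
#' spatial size. Each encoder stage applies two padding-same 3x3
#' convolutions with ReLU and a 2x2 max-pool; the bottleneck applies two
#' convolutions followed by dropout; each decoder stage upsamples (2x
#' nearest-neighbour + 3x3 convolution), concatenates the skip
#' connection at that resolution, and applies two further convolutions.
#' Weights are He-initialised.
#'
#' @param cfg a [unetConfig()].
#' @param seed optional integer seed for the weight initialisation.
#' @return a model handle (list with \code{cfg} and named parameter
#'   tensors).
#' @export
buildUnet <- function(cfg = unetConfig(), seed = NULL) {
  stopifnot(inherits(cfg, "UNetConfig"))
  build <- function() {
    p <- list()
    cin <- 1L
    for (i in seq_len(cfg$depth)) {
      f <- cfg$baseFilters * 2^(i - 1)
      p[[sprintf("enc%d_conv1", i)]] <- .heConv(3, cin, f)
      p[[sprintf("enc%d_conv2", i)]] <- .heConv(3, f, f)
      cin <- f
    }
    fb <- cfg$baseFilters * 2^cfg$depth
    p[["bott_conv1"]] <- .heConv(3, cin, fb)
    p[["bott_conv2"]] <- .heConv(3, fb, fb)
    up <- fb
    for (i in rev(seq_len(cfg$depth))) {
      f <- cfg$baseFilters * 2^(i - 1)
      p[[sprintf("dec%d_up", i)]] <- .heConv(3, up, f)
      p[[sprintf("dec%d_conv1", i)]] <- .heConv(3, 2 * f, f)
      p[[sprintf("dec%d_conv2", i)]] <- .heConv(3, f, f)
      up <- f
    }
    p[["final"]] <- .heConv(1, cfg$baseFilters, 1L)
    p
  }
  params <- if (is.null(seed)) build() else .withSeed(seed, build())
  structure(list(cfg = cfg, params = params), class = "UNetModel")
}

#' Number of trainable parameters
#' @param model a [buildUnet()] model.
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass. x: H x W x 1 array (or matrix). Returns list(prob, cache)
# when withCache, else the probability matrix.
.unetForward <- function(model, x, training = FALSE, withCache = FALSE) {
  cfg <- model$cfg; p <- model$params
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  cache <- list(); skips <- list()
  relu <- function(z) pmax(z, 0)
  runConv <- function(name, x, act = TRUE) {
    cv <- .convForward(x, p[[name]])
    a <- if (act) relu(cv$out) else cv$out
    if (withCache) cache[[name]] <<- list(M = cv$M, inDim = cv$inDim, act = a)
    a
  }
  for (i in seq_len(cfg$depth)) {
    x <- runConv(sprintf("enc%d_conv1", i), x)
    x <- runConv(sprintf("enc%d_conv2", i), x)
    skips[[i]] <- x
    pl <- .poolForward(x)
    if (withCache) cache[[sprintf("pool%d", i)]] <- pl[c("arg", "inDim")]
    x <- pl$out
  }
  x <- runConv("bott_conv1", x)
  x <- runConv("bott_conv2", x)
  if (training && cfg$dropoutRate > 0) {
    mask <- array(stats::runif(length(x)) >= cfg$dropoutRate, dim(x)) /
      (1 - cfg$dropoutRate)
    x <- x * mask
    if (withCache) cache[["dropout"]] <- mask
  }
  for (i in rev(seq_len(cfg$depth))) {
    x <- .upsample2(x)
    x <- runConv(sprintf("dec%d_up", i), x)
    nf <- dim(x)[3]
    x <- array(c(skips[[i]], x), c(dim(x)[1], dim(x)[2], 2 * nf))
    x <- runConv(sprintf("dec%d_conv1", i), x)
    x <- runConv(sprintf("dec%d_conv2", i), x)
  }
  z <- runConv("final", x, act = FALSE)
  prob <- 1 / (1 + exp(-z))
  if (withCache) { cache[["prob"]] <- prob; list(prob = prob, cache = cache) }
  else prob[, , 1]
}

# Backward pass from dL/dprob; returns gradients named like params.
.unetBackward <- function(model, cache, dProb) {
  cfg <- model$cfg; p <- model$params
  grads <- list()
  prob <- cache$prob
  dz <- dProb * prob * (1 - prob)  # sigmoid
  backConv <- function(name, dOut, act = TRUE) {
    cc <- cache[[name]]
    if (act) dOut <- dOut * (cc$act > 0)
    bk <- .convBackward(cc, p[[name]], dOut)
    grads[[name]] <<- list(dW = bk$dW, db = bk$db)
    bk$dX
  }
  # the forward decoder runs coarse -> fine (stage depth .. 1), so the
  # backward sweep visits stage 1 first and hands dx up to the next
  # coarser stage, ending at the bottleneck
  dx <- backConv("final", dz, act = FALSE)
  dSkips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dx <- backConv(sprintf("dec%d_conv2", i), dx)
    dx <- backConv(sprintf("dec%d_conv1", i), dx)
    nf <- dim(dx)[3] / 2
    dSkips[[i]] <- dx[, , seq_len(nf), drop = FALSE]
    dUp <- dx[, , nf + seq_len(nf), drop = FALSE]
    dx <- .upsampleBackward(backConv(sprintf("dec%d_up", i), dUp))
  }
  if (!is.null(cache[["dropout"]])) dx <- dx * cache[["dropout"]]
  dx <- backConv("bott_conv2", dx)
  dx <- backConv("bott_conv1", dx)
  for (i in rev(seq_len(cfg$depth))) {
    dx <- .poolBackward(cache[[sprintf("pool%d", i)]], dx)
    dx <- dx + dSkips[[i]]
    dx <- backConv(sprintf("enc%d_conv2", i), dx)
    dx <- backConv(sprintf("enc%d_conv1", i), dx)
  }
  grads
}

#' Dice loss
#'
#' \code{1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) +
#' eps)}: a smoothed, differentiable complement of the Dice similarity
#' coefficient. Equals \code{1 - dsc(...)} exactly on binary inputs as
#' \code{eps} tends to 0.
#'
#' @param pred predicted probabilities.
#' @param truth binary reference of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar loss in [0, 1].
#' @examples
#' t <- matrix(0, 4, 4); t[1:2, 1:2] <- 1
#' p <- t; p[3, 1:2] <- 1   # covers truth plus 2 extra pixels
#' diceLoss(p, t)           # 1 - 8/10 = 0.2
#' @export
diceLoss <- function(pred, truth, eps = 1e-6) {
  if (!identical(dim(pred), dim(truth)))
    stop("domain error: pred and truth shapes differ")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

.diceLossGrad <- function(pred, truth, eps = 1e-6) {
  s <- sum(pred) + sum(truth) + eps
  inter <- 2 * sum(pred * truth) + eps
  -(2 * truth * s - inter) / s^2
}
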