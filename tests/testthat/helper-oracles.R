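# Independent reference implementations used as oracles. These are
# deliberately written as naive per-pixel loops, sharing no code with
# the package internals they check.

# Bilinear resize, pixel-center convention, per-pixel loop.
oracleBilinearResize <- function(img, outH, outW) {
  inH <- nrow(img); inW <- ncol(img)
  out <- matrix(0, outH, outW)
  for (i in seq_len(outH)) {
    for (j in seq_len(outW)) {
      sr <- (i - 0.5) * inH / outH - 0.5
      sc <- (j - 0.5) * inW / outW - 0.5
      sr <- min(max(sr, 0), inH - 1)
      sc <- min(max(sc, 0), inW - 1)
      r0 <- floor(sr); c0 <- floor(sc)
      r1 <- min(r0 + 1, inH - 1); c1 <- min(c0 + 1, inW - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- img[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
        img[r1 + 1, c0 + 1] * fr * (1 - fc) +
        img[r0 + 1, c1 + 1] * (1 - fr) * fc +
        img[r1 + 1, c1 + 1] * fr * fc
    }
  }
  out
}

# Even-odd point-in-polygon (boundary inclusive), one pixel at a time.
oraclePointInPolygon <- function(px, py, verts, tol = 1e-9) {
  nv <- nrow(verts)
  inside <- FALSE
  for (k in seq_len(nv)) {
    a <- verts[k, ]; b <- verts[k %% nv + 1, ]
    # on-segment check
    L2 <- sum((b - a)^2)
    t <- if (L2 == 0) 0 else
      min(max(((px - a[1]) * (b[1] - a[1]) + (py - a[2]) * (b[2] - a[2])) / L2, 0), 1)
    if ((px - (a[1] + t * (b[1] - a[1])))^2 +
        (py - (a[2] + t * (b[2] - a[2])))^2 <= tol) return(TRUE)
    if ((a[2] > py) != (b[2] > py)) {
      xi <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (px < xi) inside <- !inside
    }
  }
  inside
}

oracleRasterize <- function(verts, shape) {
  out <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      out[i, j] <- as.numeric(oraclePointInPolygon(j - 1, i - 1, verts))
  out
}

# Border flood fill over 4-connected background; enclosed background
# becomes foreground.
oracleFillHoles <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  visited <- matrix(FALSE, nr, nc)
  queue <- list()
  push <- function(i, j) {
    if (i >= 1 && i <= nr && j >= 1 && j <= nc && !visited[i, j] &&
        mask[i, j] == 0) {
      visited[i, j] <<- TRUE
      queue[[length(queue) + 1]] <<- c(i, j)
    }
  }
  for (i in seq_len(nr)) { push(i, 1); push(i, nc) }
  for (j in seq_len(nc)) { push(1, j); push(nr, j) }
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    push(p[1] - 1, p[2]); push(p[1] + 1, p[2])
    push(p[1], p[2] - 1); push(p[1], p[2] + 1)
  }
  out <- mask
  out[mask == 0 & !visited] <- 1
  out
}

# 8-connected component labeling by depth-first search.
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (mask[si, sj] == 1 && lab[si, sj] == 0L) {
      cur <- cur + 1L
      stack <- list(c(si, sj)); lab[si, sj] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
              mask[i, j] == 1 && lab[i, j] == 0L) {
            lab[i, j] <- cur
            stack[[length(stack) + 1]] <- c(i, j)
          }
        }
      }
    }
  }
  lab
}

oracleDespeckle <- function(mask, minSize) {
  lab <- oracleLabel8(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  out <- mask
  for (k in which(sizes < minSize)) out[lab == k] <- 0
  out
}

randomMask <- function(nr = 32, nc = 32, p = 0.4) {
  matrix(as.numeric(rbinom(nr * nc, 1, p)), nr, nc)
}

# Small phantom stack fixtures
tinyGeometry <- function(nr = 16, nc = 16, ...) {
  seriesGeometry(1, 1, 1, nRows = nr, nCols = nc, ...)
}
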