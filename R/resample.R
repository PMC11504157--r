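# Internal resampling primitives. Pixel-center convention throughout:
# 0-based indices, pixel (i, j) has its center at coordinate (i, j), and
# an output pixel center maps to source coordinate
#   src = (dst + 0.5) * n_in / n_out - 0.5.

# Separable bilinear resize with edge clamping.
.bilinearResample <- function(img, outH, outW) {
  inH <- nrow(img); inW <- ncol(img)
  r <- (seq_len(outH) - 0.5) * inH / outH - 0.5
  cc <- (seq_len(outW) - 0.5) * inW / outW - 0.5
  r <- pmin(pmax(r, 0), inH - 1)
  cc <- pmin(pmax(cc, 0), inW - 1)
  r0 <- floor(r); r1 <- pmin(r0 + 1, inH - 1); fr <- r - r0
  c0 <- floor(cc); c1 <- pmin(c0 + 1, inW - 1); fc <- cc - c0
  # rows pass
  a <- img[r0 + 1, , drop = FALSE] * (1 - fr) + img[r1 + 1, , drop = FALSE] * fr
  # columns pass
  a[, c0 + 1, drop = FALSE] * rep(1 - fc, each = outH) +
    a[, c1 + 1, drop = FALSE] * rep(fc, each = outH)
}

# Nearest-neighbour resize (round-half-up on the source coordinate).
.nearestResample <- function(img, outH, outW) {
  inH <- nrow(img); inW <- ncol(img)
  r <- floor((seq_len(outH) - 0.5) * inH / outH - 0.5 + 0.5)
  cc <- floor((seq_len(outW) - 0.5) * inW / outW - 0.5 + 0.5)
  r <- pmin(pmax(r, 0), inH - 1)
  cc <- pmin(pmax(cc, 0), inW - 1)
  img[r + 1, cc + 1, drop = FALSE]
}

# Sample img at source coordinates (sr, sc) (0-based, same length as the
# output grid), bilinear or nearest, fill = 0 outside the canvas.
.sampleAt <- function(img, sr, sc, outH, outW, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  inH <- nrow(img); inW <- ncol(img)
  if (filter == "nearest") {
    ri <- floor(sr + 0.5); ci <- floor(sc + 0.5)
    ok <- ri >= 0 & ri <= inH - 1 & ci >= 0 & ci <= inW - 1
    out <- numeric(outH * outW)
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    ok <- sr >= 0 & sr <= inH - 1 & sc >= 0 & sc <= inW - 1
    out <- numeric(outH * outW)
    if (any(ok)) {
      r <- sr[ok]; cc <- sc[ok]
      r0 <- floor(r); r1 <- pmin(r0 + 1, inH - 1); fr <- r - r0
      c0 <- floor(cc); c1 <- pmin(c0 + 1, inW - 1); fc <- cc - c0
      v <- img[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
           img[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
           img[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
           img[cbind(r1 + 1, c1 + 1)] * fr * fc
      out[ok] <- v
    }
  }
  matrix(out, outH, outW)
}
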