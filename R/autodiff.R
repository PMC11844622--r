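# Minimal reverse-mode automatic differentiation on a tape.
#
# The training code needs exact gradients for a handful of array operations
# (3x3/1x1 convolution, pooling, upsampling, window attention, layer norm,
# the loss terms). No deep-learning framework is available in this stack, so
# a small tape-based engine is provided here: every operation records its
# inputs and a backward closure; agBackward() sweeps the tape in reverse.
# All gradients are verified against central finite differences in the test
# suite. Values are plain numeric arrays; one tape per forward pass.

agTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

agNode <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

agAccum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

## Leaf for a parameter array or a constant input.
agLeaf <- function(tape, val) agNode(tape, val)
agConst <- agLeaf

## Reverse sweep from a scalar loss node.
agBackward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

agRelu <- function(tape, x) {
  v <- x$val
  out <- agNode(tape, pmax(v, 0))
  out$backward <- function(g) agAccum(x, g * (v > 0))
  out
}

agSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  out <- agNode(tape, s)
  out$backward <- function(g) agAccum(x, g * s * (1 - s))
  out
}

agAdd <- function(tape, a, b) {
  out <- agNode(tape, a$val + b$val)
  out$backward <- function(g) { agAccum(a, g); agAccum(b, g) }
  out
}

## Multiply by a constant array/scalar (broadcast must be exact shape or
## scalar).
agMulConst <- function(tape, x, m) {
  out <- agNode(tape, x$val * m)
  out$backward <- function(g) agAccum(x, g * m)
  out
}

## Clamp to [0, 1]; gradient passes only inside the open interval.
agClamp01 <- function(tape, x) {
  v <- x$val
  out <- agNode(tape, pmin(pmax(v, 0), 1))
  out$backward <- function(g) agAccum(x, g * (v > 0 & v < 1))
  out
}

## ---- shape ----------------------------------------------------------------

## (H, W, C) array <-> (H*W) x C matrix; column-major layout makes this a
## pure dim change.
agAsMatrix <- function(tape, x) {
  d <- dim(x$val)
  out <- agNode(tape, matrix(x$val, d[1] * d[2], d[3]))
  out$backward <- function(g) agAccum(x, array(g, d))
  out
}

agAsArray <- function(tape, x, h, w) {
  cOut <- ncol(x$val)
  out <- agNode(tape, array(x$val, c(h, w, cOut)))
  out$backward <- function(g) agAccum(x, matrix(g, h * w, cOut))
  out
}

## Row gather with unique indices (window partition / un-partition, line
## subsetting). Backward scatters into the source rows.
agGatherRows <- function(tape, x, idx) {
  nr <- nrow(x$val)
  out <- agNode(tape, x$val[idx, , drop = FALSE])
  out$backward <- function(g) {
    dx <- matrix(0, nr, ncol(x$val))
    dx[idx, ] <- g
    agAccum(x, dx)
  }
  out
}

agConcatC <- function(tape, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  out <- agNode(tape, array(c(a$val, b$val), c(da[1], da[2], da[3] + db[3])))
  out$backward <- function(g) {
    agAccum(a, g[, , seq_len(da[3]), drop = FALSE])
    agAccum(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  }
  out
}

## ---- convolution ----------------------------------------------------------

## Cached im2col index maps keyed by geometry.
.im2colCache <- new.env(parent = emptyenv())

im2colIndex <- function(h, w, cin, k) {
  key <- paste(h, w, cin, k, sep = "_")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  rr <- rep(seq_len(h), times = w) + p
  cc <- rep(seq_len(w), each = h) + p
  cols <- vector("list", k * k * cin)
  j <- 0L
  for (ch in seq_len(cin)) {
    base <- (ch - 1L) * hp * wp
    for (dx in seq.int(-p, p)) {
      for (dy in seq.int(-p, p)) {
        j <- j + 1L
        cols[[j]] <- base + (cc + dx - 1L) * hp + (rr + dy)
      }
    }
  }
  idx <- matrix(unlist(cols), nrow = h * w)
  .im2colCache[[key]] <- idx
  idx
}

## 2D convolution, stride 1, "same" zero padding. x: (H, W, Cin) node;
## wgt: (k*k*Cin) x Cout node; bias: length-Cout node.
agConv2d <- function(tape, x, wgt, bias, k = 3L) {
  d <- dim(x$val); h <- d[1]; w <- d[2]; cin <- d[3]
  cout <- ncol(wgt$val)
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    padded <- array(0, c(h + 2L * p, w + 2L * p, cin))
    padded[p + seq_len(h), p + seq_len(w), ] <- x$val
  } else padded <- x$val
  idx <- im2colIndex(h, w, cin, k)
  patches <- padded[idx]
  dim(patches) <- c(h * w, k * k * cin)
  outm <- patches %*% wgt$val
  outm <- sweep(outm, 2, bias$val, "+")
  dim(outm) <- c(h, w, cout)
  out <- agNode(tape, outm)
  out$backward <- function(g) {
    dim(g) <- c(h * w, cout)
    agAccum(wgt, crossprod(patches, g))
    agAccum(bias, colSums(g))
    dP <- g %*% t(wgt$val)
    ## col2im: accumulate per spatial offset (columns are ordered offset-
    ## fastest within each input channel)
    dpad <- array(0, c(h + 2L * p, w + 2L * p, cin))
    o <- 0L
    for (dx in seq.int(-p, p)) {
      for (dy in seq.int(-p, p)) {
        o <- o + 1L
        slab <- dP[, (seq_len(cin) - 1L) * (k * k) + o, drop = FALSE]
        dim(slab) <- c(h, w, cin)
        rr <- p + dy + seq_len(h); cc <- p + dx + seq_len(w)
        dpad[rr, cc, ] <- array(dpad[rr, cc, ], c(h, w, cin)) + slab
      }
    }
    agAccum(x, if (p > 0L) dpad[p + seq_len(h), p + seq_len(w), , drop = FALSE]
               else dpad)
  }
  out
}

## ---- pooling / upsampling -------------------------------------------------

## 2x2 average pooling (H, W even).
agAvgPool2 <- function(tape, x) {
  d <- dim(x$val); h <- d[1]; w <- d[2]
  o <- seq.int(1L, h, 2L); e <- o + 1L
  oc <- seq.int(1L, w, 2L); ec <- oc + 1L
  v <- (x$val[o, oc, , drop = FALSE] + x$val[e, oc, , drop = FALSE] +
        x$val[o, ec, , drop = FALSE] + x$val[e, ec, , drop = FALSE]) / 4
  out <- agNode(tape, v)
  out$backward <- function(g) {
    dx <- array(0, d)
    q <- g / 4
    dx[o, oc, ] <- q; dx[e, oc, ] <- q; dx[o, ec, ] <- q; dx[e, ec, ] <- q
    agAccum(x, dx)
  }
  out
}

## 2x nearest-neighbour upsampling.
agUpsample2 <- function(tape, x) {
  d <- dim(x$val); h <- d[1]; w <- d[2]
  ri <- rep(seq_len(h), each = 2L)
  ci <- rep(seq_len(w), each = 2L)
  out <- agNode(tape, x$val[ri, ci, , drop = FALSE])
  out$backward <- function(g) {
    o <- seq.int(1L, 2L * h, 2L); e <- o + 1L
    oc <- seq.int(1L, 2L * w, 2L); ec <- oc + 1L
    agAccum(x, g[o, oc, , drop = FALSE] + g[e, oc, , drop = FALSE] +
               g[o, ec, , drop = FALSE] + g[e, ec, , drop = FALSE])
  }
  out
}

## ---- dense / normalization / attention ------------------------------------

agLinear <- function(tape, x, wgt, bias) {
  outm <- x$val %*% wgt$val
  outm <- sweep(outm, 2, bias$val, "+")
  out <- agNode(tape, outm)
  out$backward <- function(g) {
    agAccum(wgt, crossprod(x$val, g))
    agAccum(bias, colSums(g))
    agAccum(x, g %*% t(wgt$val))
  }
  out
}

## Row-wise layer normalization of an N x C matrix with learned gain/bias.
agLayerNorm <- function(tape, x, gain, bias, eps = 1e-5) {
  v <- x$val
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  outm <- sweep(xhat, 2, gain$val, "*")
  outm <- sweep(outm, 2, bias$val, "+")
  out <- agNode(tape, outm)
  out$backward <- function(g) {
    agAccum(gain, colSums(g * xhat))
    agAccum(bias, colSums(g))
    dxh <- sweep(g, 2, gain$val, "*")
    agAccum(x, inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)))
  }
  out
}

## Multi-head self-attention within contiguous windows of `tokens` rows.
## x: (nW * tokens) x C; wqkv: C x 3C; wo: C x C.
agWindowAttention <- function(tape, x, wqkv, bqkv, wo, bo, nHeads, tokens) {
  v <- x$val
  C <- ncol(v)
  dh <- C %/% nHeads
  nW <- nrow(v) %/% tokens
  qkv <- sweep(v %*% wqkv$val, 2, bqkv$val, "+")
  omat <- matrix(0, nrow(v), C)
  cacheA <- vector("list", nW * nHeads)
  scale <- 1 / sqrt(dh)
  for (w in seq_len(nW)) {
    rows <- (w - 1L) * tokens + seq_len(tokens)
    for (hd in seq_len(nHeads)) {
      colsQ <- (hd - 1L) * dh + seq_len(dh)
      Q <- qkv[rows, colsQ, drop = FALSE]
      K <- qkv[rows, C + colsQ, drop = FALSE]
      Vv <- qkv[rows, 2L * C + colsQ, drop = FALSE]
      S <- tcrossprod(Q, K) * scale
      S <- S - apply(S, 1, max)
      A <- exp(S)
      A <- A / rowSums(A)
      omat[rows, colsQ] <- A %*% Vv
      cacheA[[(w - 1L) * nHeads + hd]] <- list(A = A, Q = Q, K = K, V = Vv)
    }
  }
  outm <- sweep(omat %*% wo$val, 2, bo$val, "+")
  out <- agNode(tape, outm)
  out$backward <- function(g) {
    agAccum(wo, crossprod(omat, g))
    agAccum(bo, colSums(g))
    dO <- g %*% t(wo$val)
    dqkv <- matrix(0, nrow(v), 3L * C)
    for (w in seq_len(nW)) {
      rows <- (w - 1L) * tokens + seq_len(tokens)
      for (hd in seq_len(nHeads)) {
        colsQ <- (hd - 1L) * dh + seq_len(dh)
        cc <- cacheA[[(w - 1L) * nHeads + hd]]
        dOh <- dO[rows, colsQ, drop = FALSE]
        dV <- crossprod(cc$A, dOh)
        dA <- tcrossprod(dOh, cc$V)
        dS <- cc$A * (dA - rowSums(dA * cc$A))
        dqkv[rows, colsQ] <- dqkv[rows, colsQ] + dS %*% cc$K * scale
        dqkv[rows, C + colsQ] <- dqkv[rows, C + colsQ] +
          crossprod(dS, cc$Q) * scale
        dqkv[rows, 2L * C + colsQ] <- dqkv[rows, 2L * C + colsQ] + dV
      }
    }
    agAccum(wqkv, crossprod(v, dqkv))
    agAccum(bqkv, colSums(dqkv))
    agAccum(x, dqkv %*% t(wqkv$val))
  }
  out
}

## ---- reductions / losses --------------------------------------------------

## Mean over the frequency-encoding (column) axis of a (H, W, 1) array or
## H x W matrix: one value per PE line.
agRowMean <- function(tape, x) {
  v <- x$val
  if (length(dim(v)) == 3L) {
    stopifnot(dim(v)[3] == 1L)
    v <- v[, , 1L]
  }
  w <- ncol(v)
  out <- agNode(tape, rowMeans(v))
  out$backward <- function(g) {
    dv <- matrix(g / w, nrow = length(g), ncol = w)
    agAccum(x, if (length(dim(x$val)) == 3L) array(dv, dim(x$val)) else dv)
  }
  out
}

## Gather a subset of a vector node (unique indices).
agGatherVec <- function(tape, x, idx) {
  n <- length(x$val)
  out <- agNode(tape, x$val[idx])
  out$backward <- function(g) {
    dx <- numeric(n)
    dx[idx] <- g
    agAccum(x, dx)
  }
  out
}

## Soft Dice loss: 1 - (2 sum(v * gt) + eps) / (sum(v) + sum(gt) + eps).
agDiceLoss <- function(tape, x, gt, eps = 1e-6) {
  v <- x$val
  num <- 2 * sum(v * gt) + eps
  den <- sum(v) + sum(gt) + eps
  out <- agNode(tape, 1 - num / den)
  out$backward <- function(g)
    agAccum(x, g * (-(2 * gt * den - num) / den^2))
  out
}

## Binary cross-entropy, mean reduction, predictions clipped to
## [clip, 1 - clip] before the logs (gradient is zero in the clipped zone).
agBceLoss <- function(tape, x, gt, clip = 1e-6) {
  v <- x$val
  vc <- pmin(pmax(v, clip), 1 - clip)
  n <- length(v)
  out <- agNode(tape, -mean(gt * log(vc) + (1 - gt) * log(1 - vc)))
  out$backward <- function(g) {
    dv <- -(gt / vc - (1 - gt) / (1 - vc)) / n
    dv[v < clip | v > 1 - clip] <- 0
    agAccum(x, g * dv)
  }
  out
}

## Mean absolute error against a constant target.
agL1Loss <- function(tape, x, target) {
  d <- x$val - target
  n <- length(d)
  out <- agNode(tape, mean(abs(d)))
  out$backward <- function(g) agAccum(x, g * sign(d) / n)
  out
}

## Mean squared error against a constant target.
agMseLoss <- function(tape, x, target) {
  d <- x$val - target
  n <- length(d)
  out <- agNode(tape, mean(d^2))
  out$backward <- function(g) agAccum(x, g * 2 * d / n)
  out
}

## k-space data-consistency loss with closed-form gradient. x: (H, W, 1)
## array node holding the image estimate; target: H x W reference image;
## maskVec: per-line weights (length H), broadcast across columns. Under the
## orthonormal FFT the adjoint of the forward transform is the inverse
## transform, so d/dx mean |M (Fx - Fy)|^2 = (2/N) Re F^-1 (M^2 (Fx - Fy)).
agDcLoss <- function(tape, x, target, maskVec) {
  v <- x$val
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  h <- nrow(v); w <- ncol(v); n <- h * w
  kx <- fftCenter(stats::fft(v) / sqrt(n))
  ky <- fftCenter(stats::fft(target) / sqrt(n))
  dk <- (kx - ky) * maskVec          # mask recycles down columns (per line)
  out <- agNode(tape, sum(Mod(dk)^2) / n)
  out$backward <- function(g) {
    z <- stats::fft(fftUncenter(dk * maskVec), inverse = TRUE) / sqrt(n)
    dv <- g * (2 / n) * Re(z)
    agAccum(x, if (length(dim(x$val)) == 3L) array(dv, dim(x$val)) else dv)
  }
  out
}

## Weighted sum of scalar nodes: sum(coefs[i] * nodes[[i]]).
agWeightedSum <- function(tape, nodes, coefs) {
  out <- agNode(tape, sum(vapply(seq_along(nodes),
                                 function(i) coefs[i] * nodes[[i]]$val, 0)))
  out$backward <- function(g)
    for (i in seq_along(nodes)) agAccum(nodes[[i]], g * coefs[i])
  out
}

## Squared-difference feature loss between two nodes (same shape), mean
## reduction: mean((a - b)^2) with gradients to both.
agMseBetween <- function(tape, a, b) {
  d <- a$val - b$val
  n <- length(d)
  out <- agNode(tape, mean(d^2))
  out$backward <- function(g) {
    agAccum(a, g * 2 * d / n)
    agAccum(b, -g * 2 * d / n)
  }
  out
}
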