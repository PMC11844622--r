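# Network definitions: detection U-net, Swin-block correction U-net, and the
# randomized perceptual feature extractor. Parameters live in plain named
# lists of numeric arrays; forward passes build an autodiff graph and return
# the output node plus the leaf nodes of every parameter so the training
# loop can read gradients.

## Deterministic parameter init (He-style for conv/linear) from a seed.
heInit <- function(rng, fanIn, nr, nc) {
  matrix(rng$rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
}

#' Detection network configuration
#'
#' A U-net over a per-sample-standardized k-space representation of the
#' corrupted slice (by default log-magnitude plus its phase-encoding-axis
#' Laplacians; see \code{\link{detectionInput}}). Depth counts pooling
#' stages; width is the number of channels of the first stage.
#'
#' @param depth number of encoder pooling stages (default 2; input sides
#'   must be divisible by 2^depth).
#' @param width base channel width (default 8).
#' @param threshold binarization threshold for the predicted mask (0.5).
#' @param peripheralFrac fraction of PE lines at each k-space edge excluded
#'   from prediction and loss (default 0.05).
#' @param inputRepr input channels: "logmag_pediff" (default),
#'   "logmag_phase" or "logmag"; see \code{\link{detectionInput}}.
#' @return list of class "detectionConfig".
#' @export
detectionConfig <- function(depth = 2L, width = 8L, threshold = 0.5,
                            peripheralFrac = 0.05,
                            inputRepr = c("logmag_pediff", "logmag_phase",
                                          "logmag")) {
  inputRepr <- match.arg(inputRepr)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 threshold = threshold, peripheralFrac = peripheralFrac,
                 inputRepr = inputRepr),
            class = "detectionConfig")
}

#' Correction network configuration
#'
#' U-net backbone whose bottleneck attention is carried by Swin transformer
#' blocks (window self-attention + MLP with layer norm and residuals). The
#' loss weights default to lambda_r = 10 (L1), lambda_l = 0.5 (perceptual),
#' lambda_d = 100 (k-space data consistency).
#'
#' @param lambdaR,lambdaL,lambdaD loss weights.
#' @param depth,width U-net pooling stages / base channels.
#' @param windowSize Swin attention window (pixels, default 8).
#' @param nHeads attention heads (default 4).
#' @param nSwin number of Swin blocks at the bottleneck (default 2; the
#'   second block uses a cyclically shifted window partition).
#' @param dcMask mask fed to the data-consistency loss: the detector's
#'   binarized prediction ("predicted", default, detached from the detector's
#'   gradient path) or the ground-truth mask ("ground_truth").
#' @return list of class "correctionConfig".
#' @export
correctionConfig <- function(lambdaR = 10, lambdaL = 0.5, lambdaD = 100,
                             depth = 2L, width = 16L, windowSize = 8L,
                             nHeads = 4L, nSwin = 2L,
                             dcMask = c("predicted", "ground_truth")) {
  dcMask <- match.arg(dcMask)
  structure(list(lambdaR = lambdaR, lambdaL = lambdaL, lambdaD = lambdaD,
                 depth = as.integer(depth), width = as.integer(width),
                 windowSize = as.integer(windowSize),
                 nHeads = as.integer(nHeads), nSwin = as.integer(nSwin),
                 dcMask = dcMask),
            class = "correctionConfig")
}

## ---- U-net parameter construction -----------------------------------------

## Channel plan for a U-net of given depth/width: widths double per stage.
unetWidths <- function(depth, width) width * 2L^(0:depth)

## Parameters for a double-conv block cin -> cout -> cout.
convBlockParams <- function(rng, cin, cout) {
  list(w1 = heInit(rng, 9 * cin, 9 * cin, cout), b1 = numeric(cout),
       w2 = heInit(rng, 9 * cout, 9 * cout, cout), b2 = numeric(cout))
}

## Initialize detector parameters.
initDetector <- function(cfg, seed = 1L) {
  rng <- localRNG(seed)
  cin <- switch(cfg$inputRepr, logmag = 1L, logmag_phase = 2L,
                logmag_pediff = 3L)
  ws <- unetWidths(cfg$depth, cfg$width)
  p <- list()
  prev <- cin
  for (s in seq_len(cfg$depth + 1L)) {           # encoders + bottleneck
    p[[paste0("enc", s)]] <- convBlockParams(rng, prev, ws[s])
    prev <- ws[s]
  }
  for (s in seq.int(cfg$depth, 1L)) {            # decoders
    p[[paste0("dec", s)]] <- convBlockParams(rng, ws[s + 1L] + ws[s], ws[s])
  }
  p$head <- list(w = heInit(rng, ws[1], ws[1], 1L), b = numeric(1L))
  p
}

## Initialize corrector parameters (head starts at zero: identity residual).
initCorrector <- function(cfg, seed = 2L) {
  rng <- localRNG(seed)
  ws <- unetWidths(cfg$depth, cfg$width)
  p <- list()
  prev <- 1L
  for (s in seq_len(cfg$depth + 1L)) {
    p[[paste0("enc", s)]] <- convBlockParams(rng, prev, ws[s])
    prev <- ws[s]
  }
  cb <- ws[cfg$depth + 1L]
  for (i in seq_len(cfg$nSwin)) {
    p[[paste0("swin", i)]] <- list(
      lng1 = rep(1, cb), lnb1 = numeric(cb),
      wqkv = heInit(rng, cb, cb, 3L * cb), bqkv = numeric(3L * cb),
      wo = heInit(rng, cb, cb, cb), bo = numeric(cb),
      lng2 = rep(1, cb), lnb2 = numeric(cb),
      wm1 = heInit(rng, cb, cb, 2L * cb), bm1 = numeric(2L * cb),
      wm2 = heInit(rng, 2L * cb, 2L * cb, cb), bm2 = numeric(cb))
  }
  for (s in seq.int(cfg$depth, 1L)) {
    p[[paste0("dec", s)]] <- convBlockParams(rng, ws[s + 1L] + ws[s], ws[s])
  }
  p$head <- list(w = matrix(0, 9 * ws[1], 1L), b = numeric(1L))
  p
}

## Randomized multi-scale perceptual feature extractor: three conv stages
## with fixed He-initialized weights (never trained). First-stage filters
## are centered to zero mean (derivative-like, as in early-vision filter
## banks): this makes the metric respond to structured high-frequency
## error more than to smooth error of equal energy, the defining property
## of a perceptual distance. Deterministic for a fixed seed.
initFeatureExtractor <- function(seed = 99L, widths = c(8L, 16L, 32L)) {
  rng <- localRNG(seed)
  prev <- 1L
  p <- list()
  for (i in seq_along(widths)) {
    w <- heInit(rng, 9 * prev, 9 * prev, widths[i])
    if (i == 1L) w <- sweep(w, 2, colMeans(w))   # zero-mean (high-pass)
    p[[paste0("conv", i)]] <- list(w = w, b = numeric(widths[i]))
    prev <- widths[i]
  }
  structure(list(params = p, widths = widths, seed = seed),
            class = "featureExtractor")
}

#' Randomized perceptual feature extractor
#'
#' A small fixed-weight convolutional pyramid (He-initialized from a seed,
#' never trained) whose stage activations define the perceptual loss. A
#' learned backbone can be substituted by supplying its weights in the same
#' layout.
#'
#' @param seed init seed (default 99).
#' @param widths channels of the three stages.
#' @return object of class "featureExtractor".
#' @export
featureExtractor <- function(seed = 99L, widths = c(8L, 16L, 32L)) {
  initFeatureExtractor(seed, as.integer(widths))
}

## ---- graph builders -------------------------------------------------------

## Wrap every array of a nested parameter list into leaves; returns
## list(leaves = nested leaf list, flat = named flat list of leaves).
leafify <- function(tape, params) {
  flat <- list()
  wrap <- function(x, prefix) {
    if (is.list(x)) {
      out <- lapply(names(x), function(nm)
        wrap(x[[nm]], paste0(prefix, ".", nm)))
      names(out) <- names(x)
      out
    } else {
      lf <- agLeaf(tape, x)
      flat[[sub("^\\.", "", prefix)]] <<- lf
      lf
    }
  }
  leaves <- wrap(params, "")
  list(leaves = leaves, flat = flat)
}

convBlock <- function(tape, x, blk) {
  h <- agRelu(tape, agConv2d(tape, x, blk$w1, blk$b1))
  agRelu(tape, agConv2d(tape, h, blk$w2, blk$b2))
}

## Shared U-net trunk; returns the last decoder feature node.
unetTrunk <- function(tape, x, leaves, depth, bottleneck = NULL) {
  skips <- vector("list", depth)
  h <- x
  for (s in seq_len(depth)) {
    h <- convBlock(tape, h, leaves[[paste0("enc", s)]])
    skips[[s]] <- h
    h <- agAvgPool2(tape, h)
  }
  h <- convBlock(tape, h, leaves[[paste0("enc", depth + 1L)]])
  if (!is.null(bottleneck)) h <- bottleneck(tape, h)
  for (s in seq.int(depth, 1L)) {
    h <- agUpsample2(tape, h)
    h <- agConcatC(tape, h, skips[[s]])
    h <- convBlock(tape, h, leaves[[paste0("dec", s)]])
  }
  h
}

## Detector forward: input (H, W, C) array -> raw sigmoid map node (H, W, 1).
detectorForward <- function(tape, inputArr, leaves) {
  x <- agConst(tape, inputArr)
  h <- unetTrunk(tape, x, leaves, length(grep("^enc", names(leaves))) - 1L)
  agSigmoid(tape, agConv2d(tape, h, leaves$head$w, leaves$head$b, k = 1L))
}

## Window-partition row indices for (h, w) grid flattened column-major,
## window size ws, optional cyclic shift.
windowIndex <- function(h, w, ws, shift = 0L) {
  rows <- ((seq_len(h) - 1L + shift) %% h) + 1L
  cols <- ((seq_len(w) - 1L + shift) %% w) + 1L
  idx <- integer(h * w)
  pos <- 0L
  for (wc in seq_len(w %/% ws)) {
    for (wr in seq_len(h %/% ws)) {
      rr <- rows[(wr - 1L) * ws + seq_len(ws)]
      cc <- cols[(wc - 1L) * ws + seq_len(ws)]
      block <- outer(rr, (cc - 1L) * h, "+")
      idx[pos + seq_len(ws * ws)] <- as.integer(block)
      pos <- pos + ws * ws
    }
  }
  idx
}

swinBlock <- function(tape, x, blk, h, w, ws, nHeads, shift = 0L) {
  idx <- windowIndex(h, w, ws, shift)
  xm <- agAsMatrix(tape, x)
  xw <- agGatherRows(tape, xm, idx)
  a <- agLayerNorm(tape, xw, blk$lng1, blk$lnb1)
  a <- agWindowAttention(tape, a, blk$wqkv, blk$bqkv, blk$wo, blk$bo,
                         nHeads, ws * ws)
  xw <- agAdd(tape, xw, a)
  m <- agLayerNorm(tape, xw, blk$lng2, blk$lnb2)
  m <- agRelu(tape, agLinear(tape, m, blk$wm1, blk$bm1))
  m <- agLinear(tape, m, blk$wm2, blk$bm2)
  xw <- agAdd(tape, xw, m)
  ## un-partition: scatter rows back (inverse permutation)
  xm2 <- agGatherRows(tape, xw, order(idx))
  agAsArray(tape, xm2, h, w)
}

## Corrector forward: (H, W, 1) input node -> clamped residual output node.
correctorForward <- function(tape, inputArr, leaves, cfg) {
  h <- dim(inputArr)[1]; w <- dim(inputArr)[2]
  hb <- h %/% 2L^cfg$depth; wb <- w %/% 2L^cfg$depth
  ## largest window not exceeding the configured size that tiles the
  ## bottleneck exactly
  ws <- min(cfg$windowSize, hb, wb)
  while (ws > 1L && (hb %% ws != 0L || wb %% ws != 0L)) ws <- ws - 1L
  bottleneck <- function(tape, z) {
    for (i in seq_len(cfg$nSwin)) {
      shift <- if (i %% 2L == 0L) ws %/% 2L else 0L
      z <- swinBlock(tape, z, leaves[[paste0("swin", i)]], hb, wb, ws,
                     cfg$nHeads, shift)
    }
    z
  }
  x <- agConst(tape, inputArr)
  trunk <- unetTrunk(tape, x, leaves, cfg$depth, bottleneck)
  res <- agConv2d(tape, trunk, leaves$head$w, leaves$head$b)
  agClamp01(tape, agAdd(tape, x, res))
}

## Feature-extractor forward on a (H, W, 1) node: list of stage nodes.
extractorForward <- function(tape, xNode, feLeaves) {
  feats <- vector("list", length(feLeaves))
  h <- xNode
  for (i in seq_along(feLeaves)) {
    h <- agRelu(tape, agConv2d(tape, h, feLeaves[[i]]$w, feLeaves[[i]]$b))
    feats[[i]] <- h
    if (i < length(feLeaves)) h <- agAvgPool2(tape, h)
  }
  feats
}

## ---- optimizer -------------------------------------------------------------

adamInit <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

## One Adam update. grads: nested list matching params (NULL entries skipped).
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- lapply(names(p), function(nm)
        upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]]))
      names(out) <- names(p)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      if (is.null(g)) g <- p * 0
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  res <- upd(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

## Pull gradient arrays out of a nested leaf list.
leafGrads <- function(leaves) {
  pull <- function(x) {
    if (is.environment(x)) {
      if (is.null(x$grad)) NULL else x$grad
    } else {
      out <- lapply(x, pull)
      names(out) <- names(x)
      out
    }
  }
  pull(leaves)
}

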