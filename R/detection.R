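# Motion detection: U-net over a k-space representation of the corrupted
# slice, spatial-averaging module, and the Dice + BCE segmentation loss.

#' Spatial averaging of a 2D prediction map
#'
#' Averages a raw prediction map across the frequency-encoding (column)
#' direction and assigns the average to each k-space line, enforcing the
#' line structure of inter-line rigid motion. Applying it to an already
#' line-constant map is the identity (it is a projection).
#'
#' @param raw numeric matrix in [0, 1] (H x W).
#' @return a soft \linkS4class{LineMask} of length H.
#' @examples
#' spatialAverage(matrix(rep(c(0, 1), each = 8), 2, 8, byrow = TRUE))
#' @export
spatialAverage <- function(raw) {
  if (is(raw, "ImageSlice")) raw <- raw@pixels
  stopifnot(is.matrix(raw))
  if (any(raw < 0) || any(raw > 1))
    stop("raw prediction map must lie in [0, 1]", call. = FALSE)
  lineMask(rowMeans(raw), binary = FALSE)
}

## Included (non-peripheral) PE line indices: the outermost frac of lines at
## each k-space edge is excluded from prediction and loss.
includedLines <- function(h, peripheralFrac) {
  nEx <- ceiling(peripheralFrac * h)
  if (nEx == 0) return(seq_len(h))
  seq.int(nEx + 1L, h - nEx)
}

## Coerce mask-like input to a numeric vector/matrix.
asMaskNumeric <- function(x) {
  if (is(x, "LineMask")) x@values else x
}

#' Soft Dice loss
#'
#' \code{1 - (2 sum(mp * mgt) + eps) / (sum(mp) + sum(mgt) + eps)} with
#' \code{eps = 1e-6}. Accepts vectors, matrices or \linkS4class{LineMask}s of
#' identical shape; smooth in the prediction.
#'
#' @param mp predicted mask (values in [0, 1]).
#' @param mgt ground-truth mask.
#' @param eps stabilizer preventing division by zero.
#' @return scalar in [0, 1].
#' @export
diceLoss <- function(mp, mgt, eps = 1e-6) {
  mp <- asMaskNumeric(mp); mgt <- asMaskNumeric(mgt)
  if (length(mp) != length(mgt))
    stop("mask shapes differ", call. = FALSE)
  1 - (2 * sum(mp * mgt) + eps) / (sum(mp) + sum(mgt) + eps)
}

#' Binary cross-entropy loss (mean reduction)
#'
#' Predictions are clipped to [clip, 1 - clip] before the logarithms. The
#' reduction is the mean over elements (rather than the sum), so the
#' segmentation-loss scale does not depend on image size.
#'
#' @param mp predicted mask in [0, 1].
#' @param mgt ground-truth binary mask.
#' @param clip clipping bound for the logs (default 1e-6).
#' @return non-negative scalar.
#' @export
bceLoss <- function(mp, mgt, clip = 1e-6) {
  mp <- asMaskNumeric(mp); mgt <- asMaskNumeric(mgt)
  if (length(mp) != length(mgt))
    stop("mask shapes differ", call. = FALSE)
  vc <- pmin(pmax(mp, clip), 1 - clip)
  -mean(mgt * log(vc) + (1 - mgt) * log(1 - vc))
}

#' Combined segmentation loss (Dice + BCE)
#'
#' @inheritParams diceLoss
#' @return scalar: \code{diceLoss(mp, mgt) + bceLoss(mp, mgt)}.
#' @export
segLoss <- function(mp, mgt) diceLoss(mp, mgt) + bceLoss(mp, mgt)

#' Build the detection network input from k-space
#'
#' Channels derived from the corrupted spectrum, standardized per sample.
#' The default \code{"logmag_pediff"} combines the log-magnitude
#' \code{log(1 + |k|)} with its discrete Laplacians along the
#' phase-encoding axis at neighbour distances 1 and 2, which highlight
#' lines whose magnitude profile is inconsistent with their neighbours
#' (the signature of a spliced line) at the two scales a 3-7 line slab
#' presents. \code{"logmag_phase"} pairs the log-magnitude with the phase
#' divided by pi; \code{"logmag"} is magnitude-only.
#'
#' @param ks a \linkS4class{KSpaceSlice} (typically the corrupted spectrum).
#' @param repr "logmag_pediff" (default), "logmag_phase" or "logmag".
#' @return numeric array (H, W, channels).
#' @export
detectionInput <- function(ks, repr = c("logmag_pediff", "logmag_phase",
                                        "logmag")) {
  stopifnot(is(ks, "KSpaceSlice"))
  repr <- match.arg(repr)
  k <- ks@coeffs
  h <- nrow(k)
  lm <- log1p(Mod(k))
  lm <- (lm - mean(lm)) / (stats::sd(as.vector(lm)) + 1e-12)
  if (repr == "logmag") return(array(lm, c(dim(k), 1L)))
  if (repr == "logmag_phase")
    return(array(c(lm, Arg(k) / pi), c(dim(k), 2L)))
  shift <- function(d) lm[pmin(pmax(seq_len(h) + d, 1L), h), , drop = FALSE]
  lap <- function(d) {
    r <- lm - (shift(-d) + shift(d)) / 2
    r / (stats::sd(as.vector(r)) + 1e-12)
  }
  array(c(lm, lap(1L), lap(2L)), c(dim(k), 3L))
}

#' Create an (untrained) detection model
#'
#' @param cfg a \code{\link{detectionConfig}}.
#' @param seed parameter initialization seed.
#' @return list of class "detectorModel" with fields cfg and params.
#' @export
detectorModel <- function(cfg = detectionConfig(), seed = 1L) {
  structure(list(cfg = cfg, params = initDetector(cfg, seed)),
            class = "detectorModel")
}

## Shape guard shared by both networks.
checkDivisible <- function(h, w, depth, what) {
  f <- 2L^depth
  if (h %% f != 0L || w %% f != 0L)
    stop(sprintf(
      "%s needs sides divisible by %d; got %d x %d (pad to %d x %d)",
      what, f, h, w, ceiling(h / f) * f, ceiling(w / f) * f), call. = FALSE)
}

#' Predict the corrupted-line mask for one slice
#'
#' Runs the detection U-net on the k-space representation, applies the
#' spatial-averaging module, forces the peripheral lines to zero and
#' binarizes at the configured threshold.
#'
#' @param ks a \linkS4class{KSpaceSlice} of the corrupted slice (use
#'   \code{toKSpace} on an image, or the simulated corrupted spectrum).
#' @param model a \code{\link{detectorModel}} (trained or not).
#' @return list with \code{raw} (H x W matrix), \code{averaged} (soft
#'   \linkS4class{LineMask}, peripheral lines zeroed) and \code{binary}
#'   (binary \linkS4class{LineMask}).
#' @export
detectMask <- function(ks, model) {
  stopifnot(is(ks, "KSpaceSlice"), inherits(model, "detectorModel"))
  cfg <- model$cfg
  inp <- detectionInput(ks, cfg$inputRepr)
  h <- dim(inp)[1]; w <- dim(inp)[2]
  checkDivisible(h, w, cfg$depth, "detection U-net")
  tape <- agTape()
  lf <- leafify(tape, model$params)
  raw <- detectorForward(tape, inp, lf$leaves)
  rawMat <- raw$val[, , 1L]
  avg <- rowMeans(rawMat)
  inc <- includedLines(h, cfg$peripheralFrac)
  avg[setdiff(seq_len(h), inc)] <- 0
  list(raw = rawMat,
       averaged = lineMask(avg, binary = FALSE),
       binary = lineMask(as.numeric(avg >= cfg$threshold), binary = TRUE))
}
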