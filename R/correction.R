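# Motion correction: Swin-block U-net and the composite loss
# (weighted L1 + perceptual + k-space data consistency).

#' Create an (untrained) correction model
#'
#' The network is a residual mapping: it predicts a correction added to its
#' input and clamps the sum to [0, 1]. The output head is zero-initialized,
#' so an untrained model is the identity.
#'
#' @param cfg a \code{\link{correctionConfig}}.
#' @param seed parameter initialization seed.
#' @return list of class "correctorModel" with fields cfg and params.
#' @export
correctorModel <- function(cfg = correctionConfig(), seed = 2L) {
  structure(list(cfg = cfg, params = initCorrector(cfg, seed)),
            class = "correctorModel")
}

#' Correct a motion-corrupted slice
#'
#' @param img corrupted \linkS4class{ImageSlice}.
#' @param model a \code{\link{correctorModel}}.
#' @return corrected \linkS4class{ImageSlice} (same shape, values in [0, 1]).
#' @export
correctSlice <- function(img, model) {
  stopifnot(is(img, "ImageSlice"), inherits(model, "correctorModel"))
  p <- img@pixels
  checkDivisible(nrow(p), ncol(p), model$cfg$depth, "correction U-net")
  tape <- agTape()
  lf <- leafify(tape, model$params)
  out <- correctorForward(tape, array(p, c(dim(p), 1L)), lf$leaves,
                          model$cfg)
  new("ImageSlice", pixels = out$val[, , 1L], pixelSpacing = img@pixelSpacing)
}

## Coerce image-like input to a numeric matrix.
asPixels <- function(x) if (is(x, "ImageSlice")) x@pixels else x

#' L1 reconstruction loss (mean absolute error)
#'
#' @param xhat,xgt images (\linkS4class{ImageSlice} or matrices) of equal
#'   shape.
#' @return non-negative scalar; 0 iff the images are equal.
#' @export
l1Loss <- function(xhat, xgt) {
  a <- asPixels(xhat); b <- asPixels(xgt)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  mean(abs(a - b))
}

#' Perceptual feature loss
#'
#' Sum over extractor stages of the mean squared difference between the
#' stage activations of the two images (a squared feature-space distance in
#' the LPIPS family). Deterministic for a fixed extractor.
#'
#' @param xhat,xgt images of equal shape.
#' @param fe a \code{\link{featureExtractor}}.
#' @return non-negative scalar; 0 for identical inputs.
#' @export
lpipsLoss <- function(xhat, xgt, fe = featureExtractor()) {
  a <- asPixels(xhat); b <- asPixels(xgt)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  tape <- agTape()
  lf <- leafify(tape, fe$params)
  fa <- extractorForward(tape, agConst(tape, array(a, c(dim(a), 1L))),
                         lf$leaves)
  fb <- extractorForward(tape, agConst(tape, array(b, c(dim(b), 1L))),
                         lf$leaves)
  sum(vapply(seq_along(fa),
             function(i) mean((fa[[i]]$val - fb[[i]]$val)^2), 0))
}

#' k-space data-consistency loss
#'
#' Mean squared modulus of the masked difference between the spectra of the
#' two images: only k-space lines with nonzero mask weight contribute, so the
#' loss is invariant to any change confined to unmasked lines.
#'
#' @param xhat,xgt images of equal shape.
#' @param mask a \linkS4class{LineMask} (or numeric per-line vector).
#' @return non-negative scalar.
#' @export
dcLoss <- function(xhat, xgt, mask) {
  a <- asPixels(xhat); b <- asPixels(xgt)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  m <- asMaskNumeric(mask)
  stopifnot(length(m) == nrow(a))
  n <- length(a)
  ka <- stats::fft(a) / sqrt(n)
  kb <- stats::fft(b) / sqrt(n)
  mc <- fftUncenter(matrix(rep(m, ncol(a)), nrow(a)))[, 1L]
  sum(Mod((ka - kb) * mc)^2) / n
}

#' Composite correction loss
#'
#' \code{lambdaR * L1 + lambdaL * perceptual + lambdaD * dataConsistency}
#' with the configured weights (defaults 10 / 0.5 / 100).
#'
#' @param xhat,xgt images of equal shape.
#' @param mask \linkS4class{LineMask} for the data-consistency term.
#' @param cfg a \code{\link{correctionConfig}}.
#' @param fe a \code{\link{featureExtractor}} for the perceptual term
#'   (skipped when \code{lambdaL} is 0).
#' @return list with \code{total} and the per-term breakdown
#'   (\code{l1}, \code{lpips}, \code{dc}).
#' @export
totalLoss <- function(xhat, xgt, mask, cfg = correctionConfig(),
                      fe = featureExtractor()) {
  l1 <- l1Loss(xhat, xgt)
  lp <- if (cfg$lambdaL != 0) lpipsLoss(xhat, xgt, fe) else 0
  dc <- if (cfg$lambdaD != 0) dcLoss(xhat, xgt, mask) else 0
  combineLossTerms(l1, lp, dc, cfg)
}

#' Combine pre-computed loss terms with the configured weights
#'
#' @param l1,lpips,dc scalar loss terms.
#' @param cfg a \code{\link{correctionConfig}} supplying the lambda weights.
#' @return list with \code{total} and the per-term breakdown.
#' @export
combineLossTerms <- function(l1, lpips, dc, cfg = correctionConfig()) {
  list(total = cfg$lambdaR * l1 + cfg$lambdaL * lpips + cfg$lambdaD * dc,
       l1 = l1, lpips = lpips, dc = dc)
}
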