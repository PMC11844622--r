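# Image-quality metrics: PSNR, SSIM, NMSE, and difference maps.

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(dataRange^2 / MSE)} in dB. Identical images are reported
#' as the aggregation cap (100 dB) so that means over perfect
#' reconstructions stay finite.
#'
#' @param xhat,x images (\linkS4class{ImageSlice} or matrices) of equal
#'   shape.
#' @param dataRange dynamic range of the data (1 for normalized slices).
#' @param cap value reported for a zero-MSE pair (default 100 dB).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.5, 16, 16), matrix(0.51, 16, 16))
#' @export
psnr <- function(xhat, x, dataRange = 1, cap = 100) {
  a <- asPixels(xhat); b <- asPixels(x)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(dataRange^2 / mse))
}

#' Structural similarity index (mean SSIM)
#'
#' Gaussian-weighted SSIM with the standard constants: 11 x 11 window,
#' sigma 1.5, K1 = 0.01, K2 = 0.03, population (not sample) local moments.
#' Local statistics are computed in valid mode and the mean is taken over
#' the valid interior, so no padding convention enters the value.
#'
#' @param xhat,x images of equal shape (each side >= 11).
#' @param dataRange dynamic range (default 1).
#' @return mean SSIM in [-1, 1]; 1 iff the images are equal.
#' @export
ssim <- function(xhat, x, dataRange = 1) {
  a <- asPixels(xhat); b <- asPixels(x)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  if (min(dim(a)) < 11) stop("images must be at least 11 x 11", call. = FALSE)
  k <- gaussianKernel1d(11L, 1.5)
  mua <- separableFilterValid(a, k)
  mub <- separableFilterValid(b, k)
  saa <- separableFilterValid(a * a, k) - mua^2
  sbb <- separableFilterValid(b * b, k) - mub^2
  sab <- separableFilterValid(a * b, k) - mua * mub
  c1 <- (0.01 * dataRange)^2
  c2 <- (0.03 * dataRange)^2
  s <- ((2 * mua * mub + c1) * (2 * sab + c2)) /
       ((mua^2 + mub^2 + c1) * (saa + sbb + c2))
  mean(s)
}

#' Normalized mean square error (percent)
#'
#' \code{||xhat - x||^2 / ||x||^2 * 100}, where \code{x} is the reference.
#'
#' @param xhat estimate.
#' @param x reference image (must have nonzero energy).
#' @return NMSE in percent (>= 0; 0 iff equal).
#' @export
nmse <- function(xhat, x) {
  a <- asPixels(xhat); b <- asPixels(x)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  e <- sum(b^2)
  if (e == 0) stop("reference image has zero energy", call. = FALSE)
  100 * sum((a - b)^2) / e
}

#' Signed difference map
#'
#' Returns \code{xhat - x} and optionally renders it on a symmetric
#' diverging color scale.
#'
#' @param xhat,x images of equal shape.
#' @param plot if TRUE, draw the map with \code{graphics::image}.
#' @return numeric matrix (invisibly when plotted).
#' @export
differenceMap <- function(xhat, x, plot = FALSE) {
  a <- asPixels(xhat); b <- asPixels(x)
  if (!identical(dim(a), dim(b))) stop("image shapes differ", call. = FALSE)
  d <- a - b
  if (plot) {
    lim <- max(abs(d), 1e-12)
    cols <- grDevices::hcl.colors(65, "Blue-Red 3")
    graphics::image(t(d[nrow(d):1, , drop = FALSE]), zlim = c(-lim, lim),
                    col = cols, axes = FALSE, asp = 1)
    return(invisible(d))
  }
  d
}

#' Per-slice metric report for a set of reconstructions
#'
#' Computes PSNR, SSIM and NMSE for each prediction/reference pair and a
#' group summary with bootstrap confidence intervals.
#'
#' @param pred list of predicted \linkS4class{ImageSlice}s (or matrices).
#' @param ref list of reference slices, same length.
#' @param method,severity labels attached to the report.
#' @param ciMethod "bca" (default) or "percentile".
#' @param nBoot bootstrap iterations (default 10000).
#' @param seed bootstrap seed.
#' @return list of class "metricReport": \code{perImage} data.frame and
#'   \code{summary} data.frame (mean + CI per metric).
#' @export
metricReport <- function(pred, ref, method = "method", severity = NA,
                         ciMethod = c("bca", "percentile"),
                         nBoot = 10000L, seed = 1L) {
  stopifnot(length(pred) == length(ref), length(pred) >= 1)
  ciMethod <- match.arg(ciMethod)
  per <- data.frame(
    index = seq_along(pred),
    psnr = vapply(seq_along(pred), function(i) psnr(pred[[i]], ref[[i]]), 0),
    ssim = vapply(seq_along(pred), function(i) ssim(pred[[i]], ref[[i]]), 0),
    nmse = vapply(seq_along(pred), function(i) nmse(pred[[i]], ref[[i]]), 0))
  summ <- do.call(rbind, lapply(c("psnr", "ssim", "nmse"), function(m) {
    v <- per[[m]]
    ci <- if (length(v) >= 2)
      bootstrapCI(v, nIter = nBoot, method = ciMethod, seed = seed)
    else c(v, v)
    data.frame(metric = m, mean = mean(v), ciLow = ci[1], ciHigh = ci[2])
  }))
  summ$method <- method
  summ$severity <- severity
  structure(list(perImage = per, summary = summ, method = method,
                 severity = severity), class = "metricReport")
}
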