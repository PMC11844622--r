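# Fourier conventions and the composed rigid k-space transform.
#
# Conventions, fixed package-wide:
#   * orthonormal FFT (forward and inverse both scaled by 1/sqrt(H*W)), so
#     Parseval's identity holds with unit constant;
#   * k-space is DC-centered everywhere a KSpaceSlice is visible (the shift
#     is internal);
#   * phase encoding runs along rows (axis 1): one row = one k-space line;
#   * rotations are about the geometric image center ((H+1)/2, (W+1)/2 in
#     1-based coordinates); interpolation is bilinear with zero fill.

#' Forward Fourier transform of an image slice
#'
#' Computes the DC-centered 2D Fourier coefficients of a slice under the
#' orthonormal normalization, so that image-domain and k-space energies are
#' equal (Parseval).
#'
#' @param img an \linkS4class{ImageSlice}.
#' @return a \linkS4class{KSpaceSlice}.
#' @examples
#' img <- generatePhantom(phantomSpec(size = 64, seed = 1))
#' ks <- toKSpace(img)
#' sum(pixels(img)^2) - sum(Mod(coeffs(ks))^2)  # ~0
#' @export
toKSpace <- function(img) {
  stopifnot(is(img, "ImageSlice"))
  p <- img@pixels
  if (!all(is.finite(p)))
    stop(sprintf("non-finite pixels in %d x %d input slice", nrow(p), ncol(p)),
         call. = FALSE)
  k <- fftCenter(stats::fft(p) / sqrt(length(p)))
  new("KSpaceSlice", coeffs = k, pixelSpacing = img@pixelSpacing)
}

## Internal: complex image from centered k-space (orthonormal inverse).
ifft2Centered <- function(kc) {
  stats::fft(fftUncenter(kc), inverse = TRUE) / sqrt(length(kc))
}

#' Inverse Fourier transform back to image space
#'
#' Reconstructs an image slice from DC-centered k-space. For a conjugate-
#' symmetric spectrum the result is real; after motion corruption the
#' spectrum loses conjugate symmetry and the reconstruction acquires an
#' imaginary component, which is discarded and reported in the slice's
#' \code{imagResidue}. \code{part = "magnitude"} returns the magnitude image
#' instead of the real part (used for corrupted spectra).
#'
#' @param ks a \linkS4class{KSpaceSlice}.
#' @param part "real" (default) or "magnitude".
#' @return an \linkS4class{ImageSlice}.
#' @export
fromKSpace <- function(ks, part = c("real", "magnitude")) {
  stopifnot(is(ks, "KSpaceSlice"))
  part <- match.arg(part)
  z <- ifft2Centered(ks@coeffs)
  res <- max(abs(Im(z)))
  px <- if (part == "magnitude") Mod(z) else Re(z)
  new("ImageSlice", pixels = px, pixelSpacing = ks@pixelSpacing,
      imagResidue = res)
}

## Internal: rigid warp of a plain (possibly complex) matrix.
## order "translate_rotate" applies the translation first, then the rotation
## (the composition used inside the k-space motion operator); the alternative
## applies rotation first. Inverse mapping + bilinear sampling, zero fill.
warpRigid <- function(m, thetaDeg, txPx, tyPx,
                      order = c("translate_rotate", "rotate_translate")) {
  order <- match.arg(order)
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- thetaDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  ## output grid coordinates
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  if (order == "translate_rotate") {
    ## out = R(T(in)): src = T^-1(R^-1(dst))
    dy <- rr - cy; dx <- cc - cx
    ry <- -st * dx + ct * dy        # R^-1 = R(-theta)
    rx <-  ct * dx + st * dy
    srcR <- ry + cy - tyPx
    srcC <- rx + cx - txPx
  } else {
    ## out = T(R(in)): src = R^-1(T^-1(dst))
    dy <- rr - cy - tyPx; dx <- cc - cx - txPx
    srcR <- -st * dx + ct * dy + cy
    srcC <-  ct * dx + st * dy + cx
  }
  if (is.complex(m)) {
    re <- bilinearSample(Re(m), srcR, srcC)
    im <- bilinearSample(Im(m), srcR, srcC)
    matrix(complex(real = re, imaginary = im), h, w)
  } else {
    matrix(bilinearSample(m, srcR, srcC), h, w)
  }
}

#' Rigid in-plane transform of an image slice
#'
#' Rotates about the geometric image center and translates, with bilinear
#' interpolation and zero fill outside the grid. Translations are given in mm
#' and converted to pixels via the slice's \code{pixelSpacing}. The default
#' composition applies the translation first and the rotation second,
#' matching the k-space motion operator; set \code{order} to change it.
#'
#' @param img an \linkS4class{ImageSlice}.
#' @param thetaDeg rotation in degrees (|theta| <= 180).
#' @param txMm,tyMm translation in mm along columns (x) and rows (y).
#' @param order "translate_rotate" (default) or "rotate_translate".
#' @return an \linkS4class{ImageSlice}.
#' @export
rigidTransformImage <- function(img, thetaDeg, txMm, tyMm,
                                order = c("translate_rotate",
                                          "rotate_translate")) {
  stopifnot(is(img, "ImageSlice"))
  if (abs(thetaDeg) > 180) stop("|thetaDeg| must be <= 180", call. = FALSE)
  order <- match.arg(order)
  if (thetaDeg == 0 && txMm == 0 && tyMm == 0) return(img)
  sp <- img@pixelSpacing
  out <- warpRigid(img@pixels, thetaDeg, txMm / sp, tyMm / sp, order)
  new("ImageSlice", pixels = out, pixelSpacing = sp,
      imagResidue = img@imagResidue)
}

#' Rigid motion operator in k-space
#'
#' The composed transform applied to a k-space slab during motion simulation:
#' inverse Fourier transform, rigid transform in image space (translate, then
#' rotate), forward Fourier transform. With zero motion parameters it is the
#' identity on the coefficient grid.
#'
#' @param ks a \linkS4class{KSpaceSlice}.
#' @param thetaDeg,txMm,tyMm rigid motion parameters.
#' @param order image-domain composition order, see
#'   \code{\link{rigidTransformImage}}.
#' @return a \linkS4class{KSpaceSlice}.
#' @export
kspaceRigid <- function(ks, thetaDeg, txMm, tyMm,
                        order = c("translate_rotate", "rotate_translate")) {
  stopifnot(is(ks, "KSpaceSlice"))
  order <- match.arg(order)
  if (thetaDeg == 0 && txMm == 0 && tyMm == 0) return(ks)
  sp <- ks@pixelSpacing
  z <- ifft2Centered(ks@coeffs)   # complex image
  zt <- warpRigid(z, thetaDeg, txMm / sp, tyMm / sp, order)
  k <- fftCenter(stats::fft(zt) / sqrt(length(zt)))
  new("KSpaceSlice", coeffs = k, pixelSpacing = sp)
}
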