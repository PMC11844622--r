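# Constructors and accessors for the core data classes.

#' Create an ImageSlice
#'
#' @param pixels numeric matrix (H x W), H, W >= 8.
#' @param pixelSpacing mm per pixel (default 1).
#' @param normalize if TRUE, min-max normalize pixel values to [0, 1].
#' @param imagResidue discarded imaginary residue (internal use).
#' @return an \linkS4class{ImageSlice}.
#' @examples
#' img <- imageSlice(matrix(runif(64 * 64), 64))
#' @export
imageSlice <- function(pixels, pixelSpacing = 1, normalize = FALSE,
                       imagResidue = 0) {
  stopIfNotFinite(pixels, "image pixels")
  if (normalize) {
    rng <- range(pixels)
    pixels <- if (diff(rng) > 0) (pixels - rng[1]) / diff(rng)
              else pixels * 0
  }
  new("ImageSlice", pixels = pixels, pixelSpacing = pixelSpacing,
      imagResidue = imagResidue)
}

#' Create a binary or soft per-line mask
#'
#' @param values numeric vector in [0, 1], one value per PE line.
#' @param binary logical; assert values are exactly 0/1.
#' @return a \linkS4class{LineMask}.
#' @export
lineMask <- function(values, binary = all(values %in% c(0, 1))) {
  new("LineMask", values = as.numeric(values), binary = binary)
}

#' Create a motion event
#'
#' @param thetaDeg rotation (degrees).
#' @param txMm,tyMm translation (mm) along columns / rows.
#' @param slabStart first PE line of the slab (1-based).
#' @param slabWidth slab width in lines.
#' @return a \linkS4class{MotionEvent}.
#' @export
motionEvent <- function(thetaDeg, txMm, tyMm, slabStart, slabWidth) {
  new("MotionEvent", thetaDeg = thetaDeg, txMm = txMm, tyMm = tyMm,
      slabStart = as.integer(slabStart), slabWidth = as.integer(slabWidth))
}

#' Pixel matrix of an ImageSlice
#' @param x an ImageSlice.
#' @return numeric matrix.
#' @export
pixels <- function(x) {
  stopifnot(is(x, "ImageSlice"))
  x@pixels
}

#' Complex coefficient matrix of a KSpaceSlice
#' @param x a KSpaceSlice.
#' @return complex matrix (DC-centered).
#' @export
coeffs <- function(x) {
  stopifnot(is(x, "KSpaceSlice"))
  x@coeffs
}

#' Per-line values of a LineMask
#' @param x a LineMask.
#' @return numeric vector.
#' @export
maskValues <- function(x) {
  stopifnot(is(x, "LineMask"))
  x@values
}

#' Broadcast a LineMask to a 2D matrix
#'
#' Repeats each per-line value across the frequency-encoding (column)
#' direction.
#'
#' @param x a LineMask.
#' @param width number of columns of the target grid.
#' @return numeric matrix length(x) x width.
#' @export
broadcastMask <- function(x, width) {
  stopifnot(is(x, "LineMask"))
  matrix(rep(x@values, width), nrow = length(x@values), ncol = width)
}

#' Train / test indices of a paired archive
#' @param x a PairedMotionData.
#' @return integer vector.
#' @export
trainIndices <- function(x) {
  stopifnot(is(x, "PairedMotionData"))
  x@trainIdx
}

#' @rdname trainIndices
#' @export
testIndices <- function(x) {
  stopifnot(is(x, "PairedMotionData"))
  x@testIdx
}

#' Clean slices of a paired archive
#' @param x a PairedMotionData.
#' @return list of ImageSlice.
#' @export
cleanSlices <- function(x) {
  stopifnot(is(x, "PairedMotionData"))
  x@clean
}

#' Corrupted slices / ground-truth masks / events for one severity
#' @param x a PairedMotionData.
#' @param severity one of the severities stored in the archive.
#' @return list of ImageSlice, LineMask or MotionEvent lists respectively.
#' @export
corruptedSlices <- function(x, severity) {
  stopifnot(is(x, "PairedMotionData"))
  if (!severity %in% names(x@corrupted))
    stop(sprintf("severity '%s' not in archive (has: %s)", severity,
                 paste(names(x@corrupted), collapse = ", ")), call. = FALSE)
  x@corrupted[[severity]]
}

#' @rdname corruptedSlices
#' @export
groundTruthMasks <- function(x, severity) {
  stopifnot(is(x, "PairedMotionData"))
  x@masks[[severity]]
}

#' @rdname corruptedSlices
#' @export
motionEvents <- function(x, severity) {
  stopifnot(is(x, "PairedMotionData"))
  x@events[[severity]]
}
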