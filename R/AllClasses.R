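#' @import methods
NULL

#' ImageSlice: a 2D magnitude MR image
#'
#' Container for one 2D magnitude brain MR slice. Pixel values of clean input
#' slices are normalized to [0, 1] at load/construction time; values derived
#' from corrupted spectra (Gibbs overshoot of ringing artifacts) may exceed 1
#' slightly and are kept as computed unless clamped by the caller.
#'
#' @slot pixels numeric matrix (H x W), finite, H and W >= 8. Rows index the
#'   phase-encoding direction of the corresponding k-space grid.
#' @slot pixelSpacing physical pixel size in mm per pixel, used to convert
#'   translations in mm into pixels (default 1 mm/px).
#' @slot imagResidue largest absolute imaginary component discarded when the
#'   slice was reconstructed from k-space (0 for slices born in image space).
#'   A value above ~1e-6 signals an asymmetric spectrum, expected after
#'   motion corruption.
#' @export
setClass("ImageSlice",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 imagResidue = "numeric"),
  prototype(pixelSpacing = 1, imagResidue = 0),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 8 || ncol(p) < 8) return("image must be at least 8 x 8")
    if (!all(is.finite(p))) return("pixels contain non-finite values")
    if (length(object@pixelSpacing) != 1 || object@pixelSpacing <= 0)
      return("pixelSpacing must be a single positive number")
    TRUE
  })

#' KSpaceSlice: DC-centered 2D k-space
#'
#' Complex Fourier coefficients of one slice under the orthonormal transform
#' convention, DC-centered (the zero-frequency coefficient sits at row
#' floor(H/2)+1, column floor(W/2)+1). Phase encoding runs along rows (axis 1):
#' one row = one acquired k-space line.
#'
#' @slot coeffs complex matrix (H x W), DC-centered.
#' @slot pixelSpacing mm per pixel of the underlying image grid.
#' @export
setClass("KSpaceSlice",
  representation(coeffs = "matrix", pixelSpacing = "numeric"),
  prototype(pixelSpacing = 1),
  validity = function(object) {
    if (!is.complex(object@coeffs)) return("coeffs must be a complex matrix")
    if (!all(is.finite(Re(object@coeffs))) ||
        !all(is.finite(Im(object@coeffs))))
      return("coeffs contain non-finite values")
    TRUE
  })

#' LineMask: a per-phase-encoding-line mask
#'
#' One value per k-space line (row). Binary masks mark corrupted lines;
#' real-valued masks in [0, 1] hold averaged network predictions before
#' binarization. Broadcasting to 2D repeats each value across the
#' frequency-encoding (column) direction.
#'
#' @slot values numeric vector, one entry per PE line, all in [0, 1].
#' @slot binary logical; TRUE when values are exactly 0/1.
#' @export
setClass("LineMask",
  representation(values = "numeric", binary = "logical"),
  validity = function(object) {
    v <- object@values
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      return("mask values must be finite and within [0, 1]")
    if (object@binary && !all(v %in% c(0, 1)))
      return("binary mask contains values other than 0/1")
    TRUE
  })

#' MotionEvent: one rigid motion bound to one k-space slab
#'
#' A single abrupt rigid head motion: an in-plane rotation and translation
#' applied to the k-space lines of one contiguous phase-encoding slab.
#'
#' @slot thetaDeg rotation in degrees.
#' @slot txMm,tyMm translations in mm along columns (x) and rows (y).
#' @slot slabStart first PE line of the slab (1-based).
#' @slot slabWidth number of consecutive PE lines in the slab.
#' @export
setClass("MotionEvent",
  representation(thetaDeg = "numeric", txMm = "numeric", tyMm = "numeric",
                 slabStart = "integer", slabWidth = "integer"),
  validity = function(object) {
    if (abs(object@thetaDeg) > 180) return("|thetaDeg| must be <= 180")
    if (object@slabStart < 1L) return("slabStart must be >= 1")
    if (object@slabWidth < 1L) return("slabWidth must be >= 1")
    TRUE
  })

#' SeverityPreset: sampling bounds for one motion-severity level
#'
#' The three named presets follow the simulation protocol: minor, moderate and
#' heavy corruption perturb 5, 10 and 15 k-space slabs respectively, each slab
#' 3 to 7 lines wide, with rotations within +/-7 degrees and translations
#' within +/-5 mm. A central band of PE lines (default 8 percent) is protected
#' and never corrupted.
#'
#' @slot name preset label.
#' @slot nSlabs number of motion events (slabs).
#' @slot slabWidthRange integer lower/upper bounds on slab width in lines.
#' @slot rotBoundDeg rotation bound (degrees, symmetric).
#' @slot transBoundMm translation bound (mm, symmetric, per axis).
#' @slot centerExclusionFrac fraction of central PE lines protected from
#'   corruption.
#' @export
setClass("SeverityPreset",
  representation(name = "character", nSlabs = "integer",
                 slabWidthRange = "integer", rotBoundDeg = "numeric",
                 transBoundMm = "numeric", centerExclusionFrac = "numeric"),
  validity = function(object) {
    if (object@nSlabs < 0L) return("nSlabs must be >= 0")
    if (length(object@slabWidthRange) != 2 ||
        object@slabWidthRange[1] < 1L ||
        object@slabWidthRange[2] < object@slabWidthRange[1])
      return("slabWidthRange must be increasing positive bounds")
    if (object@rotBoundDeg < 0 || object@transBoundMm < 0)
      return("bounds must be non-negative")
    if (object@centerExclusionFrac < 0 || object@centerExclusionFrac >= 1)
      return("centerExclusionFrac must be in [0, 1)")
    TRUE
  })

#' PairedMotionData: a paired clean/corrupted slice archive
#'
#' Holds clean phantom slices, their per-severity motion-corrupted versions,
#' the ground-truth line masks and the motion events that produced them, plus
#' a disjoint train/test split. Every corrupted entry carries provenance
#' (events + seed) sufficient to regenerate it bit-exactly.
#'
#' @slot clean list of ImageSlice.
#' @slot corrupted named list (one entry per severity) of lists of ImageSlice.
#' @slot masks named list (per severity) of lists of LineMask (ground truth).
#' @slot events named list (per severity) of lists of lists of MotionEvent.
#' @slot trainIdx,testIdx integer indices into clean; disjoint.
#' @slot config list snapshot of the generation parameters (incl. seed).
#' @export
setClass("PairedMotionData",
  representation(clean = "list", corrupted = "list", masks = "list",
                 events = "list", trainIdx = "integer", testIdx = "integer",
                 config = "list"),
  validity = function(object) {
    if (length(intersect(object@trainIdx, object@testIdx)) > 0)
      return("train and test indices overlap")
    n <- length(object@clean)
    if (any(c(object@trainIdx, object@testIdx) > n))
      return("split indices exceed number of slices")
    for (sv in names(object@corrupted)) {
      if (length(object@corrupted[[sv]]) != n ||
          length(object@masks[[sv]]) != n ||
          length(object@events[[sv]]) != n)
        return(sprintf("severity '%s' is not fully paired", sv))
    }
    TRUE
  })

setMethod("show", "ImageSlice", function(object) {
  p <- object@pixels
  cat(sprintf("ImageSlice %d x %d, range [%.3g, %.3g], %g mm/px\n",
              nrow(p), ncol(p), min(p), max(p), object@pixelSpacing))
  if (object@imagResidue > 1e-6)
    cat(sprintf("  (asymmetric spectrum: imaginary residue %.3g)\n",
                object@imagResidue))
})

setMethod("show", "KSpaceSlice", function(object) {
  k <- object@coeffs
  cat(sprintf(
    "KSpaceSlice %d x %d (DC-centered, PE along rows), energy %.4g\n",
    nrow(k), ncol(k), sum(Mod(k)^2)))
})

setMethod("show", "LineMask", function(object) {
  cat(sprintf("LineMask over %d PE lines (%s), %d line(s) flagged\n",
              length(object@values),
              if (object@binary) "binary" else "soft",
              sum(object@values > 0.5)))
})

setMethod("show", "MotionEvent", function(object) {
  cat(sprintf(
    "MotionEvent: theta %+.2f deg, t (%+.2f, %+.2f) mm, lines %d-%d\n",
    object@thetaDeg, object@txMm, object@tyMm,
    object@slabStart, object@slabStart + object@slabWidth - 1L))
})

setMethod("show", "SeverityPreset", function(object) {
  cat(sprintf(
    "SeverityPreset '%s': %d slabs of %d-%d lines, |rot| <= %g deg, |t| <= %g mm, center %.0f%% protected\n",
    object@name, object@nSlabs, object@slabWidthRange[1],
    object@slabWidthRange[2], object@rotBoundDeg, object@transBoundMm,
    100 * object@centerExclusionFrac))
})

setMethod("show", "PairedMotionData", function(object) {
  cat(sprintf(
    "PairedMotionData: %d slices (%d train / %d test), severities: %s\n",
    length(object@clean), length(object@trainIdx), length(object@testIdx),
    paste(names(object@corrupted), collapse = ", ")))
})
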