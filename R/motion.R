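# Rigid-motion corruption of Cartesian k-space.
#
# One motion event = one rigid transform spliced into one contiguous slab of
# phase-encoding lines. The corrupted spectrum keeps every unspliced line
# bit-identical to the motion-free spectrum — the physical basis of the
# k-space data-consistency loss.

#' Severity presets for motion simulation
#'
#' minor / moderate / heavy corrupt 5 / 10 / 15 k-space slabs, each 3-7 lines
#' wide, with rotations uniform in +/-7 degrees and translations uniform in
#' +/-5 mm per axis. All fields can be overridden.
#'
#' @param name "minor", "moderate" or "heavy".
#' @param nSlabs,slabWidthRange,rotBoundDeg,transBoundMm overrides of the
#'   preset defaults.
#' @param centerExclusionFrac fraction of central PE lines protected from
#'   corruption (default 0.08).
#' @return a \linkS4class{SeverityPreset}.
#' @examples
#' severityPreset("heavy")
#' @export
severityPreset <- function(name = c("minor", "moderate", "heavy"),
                           nSlabs = NULL, slabWidthRange = c(3L, 7L),
                           rotBoundDeg = 7, transBoundMm = 5,
                           centerExclusionFrac = 0.08) {
  name <- match.arg(name)
  if (is.null(nSlabs))
    nSlabs <- c(minor = 5L, moderate = 10L, heavy = 15L)[[name]]
  new("SeverityPreset", name = name, nSlabs = as.integer(nSlabs),
      slabWidthRange = as.integer(slabWidthRange),
      rotBoundDeg = rotBoundDeg, transBoundMm = transBoundMm,
      centerExclusionFrac = centerExclusionFrac)
}

## Internal: 1-based line indices of the protected central band.
centerBand <- function(height, frac) {
  if (frac <= 0) return(integer(0))
  nc <- max(1L, round(frac * height))
  dc <- dcIndex(height)
  lo <- dc - (nc - 1L) %/% 2L
  seq.int(lo, lo + nc - 1L)
}

#' Sample motion events for one slice
#'
#' Draws \code{nSlabs} events with widths uniform on the integer width range,
#' rotations and translations uniform within the preset bounds. Slab starts
#' are rejection-sampled until all slabs are pairwise disjoint and avoid the
#' protected central band; if the grid cannot host the configuration the
#' whole draw is retried with fresh widths, and an informative error is
#' raised when no placement exists after many attempts.
#'
#' @param preset a \linkS4class{SeverityPreset}.
#' @param height number of PE lines of the target grid.
#' @param seed integer RNG seed.
#' @return list of \linkS4class{MotionEvent}.
#' @export
sampleEvents <- function(preset, height, seed = 1L) {
  stopifnot(is(preset, "SeverityPreset"))
  n <- preset@nSlabs
  if (n == 0L) return(list())
  wr <- preset@slabWidthRange
  banned <- centerBand(height, preset@centerExclusionFrac)
  avail <- height - length(banned)
  if (avail < n * wr[1])
    stop(sprintf(
      paste0("grid with %d PE lines cannot host %d disjoint slabs of >= %d ",
             "lines outside the protected center band; need at least %d lines"),
      height, n, wr[1], n * wr[1] + length(banned)), call. = FALSE)
  rng <- localRNG(seed)
  for (attempt in seq_len(200L)) {
    widths <- wr[1] + floor(rng$runif(n, 0, wr[2] - wr[1] + 1))
    widths <- pmin(widths, wr[2])
    occupied <- rep(FALSE, height)
    occupied[banned] <- TRUE
    starts <- integer(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        s <- 1L + floor(rng$runif(1, 0, height - widths[i] + 1))
        lines <- seq.int(s, s + widths[i] - 1L)
        if (!any(occupied[lines])) {
          occupied[lines] <- TRUE
          starts[i] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      thetas <- rng$runif(n, -preset@rotBoundDeg, preset@rotBoundDeg)
      txs <- rng$runif(n, -preset@transBoundMm, preset@transBoundMm)
      tys <- rng$runif(n, -preset@transBoundMm, preset@transBoundMm)
      return(lapply(seq_len(n), function(i)
        motionEvent(thetas[i], txs[i], tys[i], starts[i], widths[i])))
    }
  }
  stop(sprintf(
    "could not place %d disjoint slabs on %d PE lines after 200 redraws",
    n, height), call. = FALSE)
}

#' Build the binary corruption mask from motion events
#'
#' The mask is 1 exactly on the union of slab lines and 0 elsewhere; lines in
#' the protected central band are forced to 0 regardless of the events.
#'
#' @param events list of \linkS4class{MotionEvent}.
#' @param height number of PE lines.
#' @param centerExclusionFrac protected central band fraction.
#' @return a binary \linkS4class{LineMask}.
#' @export
buildMask <- function(events, height, centerExclusionFrac = 0.08) {
  v <- numeric(height)
  for (ev in events) {
    lines <- seq.int(ev@slabStart, ev@slabStart + ev@slabWidth - 1L)
    lines <- lines[lines >= 1 & lines <= height]
    v[lines] <- 1
  }
  v[centerBand(height, centerExclusionFrac)] <- 0
  lineMask(v, binary = TRUE)
}

#' Splice motion-corrupted lines into k-space
#'
#' For each event the full spectrum is rigidly transformed
#' (\code{\link{kspaceRigid}}) and the slab's lines are replaced by the
#' transformed lines; all other lines stay bit-identical to the input. Lines
#' in the protected central band are never replaced.
#'
#' @param kGT motion-free \linkS4class{KSpaceSlice}.
#' @param events list of \linkS4class{MotionEvent}.
#' @param centerExclusionFrac protected central band fraction.
#' @return list with \code{kmotion} (\linkS4class{KSpaceSlice}) and
#'   \code{mask} (ground-truth binary \linkS4class{LineMask}).
#' @export
corruptKSpace <- function(kGT, events, centerExclusionFrac = 0.08) {
  stopifnot(is(kGT, "KSpaceSlice"))
  h <- nrow(kGT@coeffs)
  banned <- centerBand(h, centerExclusionFrac)
  k <- kGT@coeffs
  for (ev in events) {
    lines <- seq.int(ev@slabStart, ev@slabStart + ev@slabWidth - 1L)
    lines <- setdiff(lines[lines >= 1 & lines <= h], banned)
    if (length(lines) == 0) next
    kt <- kspaceRigid(kGT, ev@thetaDeg, ev@txMm, ev@tyMm)
    k[lines, ] <- kt@coeffs[lines, ]
  }
  list(kmotion = new("KSpaceSlice", coeffs = k,
                     pixelSpacing = kGT@pixelSpacing),
       mask = buildMask(events, h, centerExclusionFrac))
}

#' Simulate motion corruption of an image slice
#'
#' End-to-end: forward FFT, sample events for the preset, splice corrupted
#' lines, inverse FFT and take the magnitude image (the corrupted spectrum is
#' no longer conjugate-symmetric). Fully reproducible from the seed.
#'
#' @param img clean \linkS4class{ImageSlice}.
#' @param preset a \linkS4class{SeverityPreset}.
#' @param seed integer RNG seed.
#' @return list with \code{corrupted} (\linkS4class{ImageSlice}),
#'   \code{mask} (ground-truth \linkS4class{LineMask}), \code{events} and
#'   \code{kmotion}.
#' @examples
#' img <- generatePhantom(phantomSpec(size = 64, seed = 3))
#' sim <- simulateMotion(img, severityPreset("minor"), seed = 11)
#' sim$mask
#' @export
simulateMotion <- function(img, preset = severityPreset("moderate"),
                           seed = 1L) {
  stopifnot(is(img, "ImageSlice"))
  kGT <- toKSpace(img)
  events <- sampleEvents(preset, nrow(img@pixels), seed = seed)
  spl <- corruptKSpace(kGT, events, preset@centerExclusionFrac)
  corrupted <- fromKSpace(spl$kmotion, part = "magnitude")
  list(corrupted = corrupted, mask = spl$mask, events = events,
       kmotion = spl$kmotion)
}
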