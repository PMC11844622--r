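# Synthetic brain-like phantoms.
#
# The generator emulates the two features of T1-weighted brain slices that
# matter for line-wise motion corruption: a bright elliptical rim (the
# subcutaneous fat layer whose displaced copies produce ghosting) and a
# piecewise-smooth interior of overlapping tissue ellipses. Intensities are
# in [0, 1] on a zero background; compositions are randomized per seed so
# the detection task does not degenerate to one fixed image.

#' Phantom generation parameters
#'
#' @param size image side length in pixels (>= 32; default 128).
#' @param nEllipses number of interior tissue ellipses (default drawn
#'   uniformly in 4..8 per phantom).
#' @param rimIntensity intensity of the skull-like rim (default 0.95).
#' @param rimThickness rim thickness in pixels (default ~4\% of size).
#' @param seed integer RNG seed; same spec + seed is bit-reproducible.
#' @return a list of class "phantomSpec".
#' @export
phantomSpec <- function(size = 128, nEllipses = NULL, rimIntensity = 0.95,
                        rimThickness = max(2L, round(0.04 * size)),
                        seed = 1L) {
  if (size < 32) stop("phantom size must be >= 32", call. = FALSE)
  if (rimIntensity <= 0 || rimIntensity > 1)
    stop("rimIntensity must be in (0, 1]", call. = FALSE)
  structure(list(size = as.integer(size), nEllipses = nEllipses,
                 rimIntensity = rimIntensity,
                 rimThickness = as.integer(rimThickness),
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

## Internal: add one filled ellipse (value `val`) into accumulator `acc`
## taking the elementwise max, which keeps overlaps piecewise-constant.
fillEllipse <- function(acc, cy, cx, ry, rx, angle, val) {
  h <- nrow(acc); w <- ncol(acc)
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  ct <- cos(angle); st <- sin(angle)
  u <- ct * xx + st * yy
  v <- -st * xx + ct * yy
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  acc[inside] <- pmax(acc[inside], val)
  acc
}

#' Generate one brain-like phantom slice
#'
#' Deterministic for a fixed spec (including seed). The bright rim band is
#' constructed to be at least 1.5 times brighter on average than the
#' enclosed interior tissue.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return an \linkS4class{ImageSlice} with values in [0, 1].
#' @examples
#' img <- generatePhantom(phantomSpec(size = 64, seed = 7))
#' range(pixels(img))
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  n <- spec$size
  rng <- localRNG(spec$seed)
  acc <- matrix(0, n, n)
  cy <- (n + 1) / 2 + rng$runif(1, -0.02, 0.02) * n
  cx <- (n + 1) / 2 + rng$runif(1, -0.02, 0.02) * n
  ry <- n * rng$runif(1, 0.38, 0.42)
  rx <- n * rng$runif(1, 0.33, 0.37)
  ## skull-like rim: bright outer ellipse with a darker interior redrawn on
  ## top, leaving a band of rimThickness pixels
  acc <- fillEllipse(acc, cy, cx, ry, rx, 0, spec$rimIntensity)
  t <- spec$rimThickness
  interiorBase <- 0.32
  inner <- fillEllipse(matrix(0, n, n), cy, cx, ry - t, rx - t, 0, 1)
  acc[inner == 1] <- interiorBase
  ## interior tissue ellipses, darker than the rim by construction
  ne <- if (is.null(spec$nEllipses)) rng$sample(4:8, 1) else spec$nEllipses
  for (i in seq_len(ne)) {
    ecy <- cy + rng$runif(1, -0.45, 0.45) * (ry - t)
    ecx <- cx + rng$runif(1, -0.45, 0.45) * (rx - t)
    ery <- rng$runif(1, 0.08, 0.3) * ry
    erx <- rng$runif(1, 0.08, 0.3) * rx
    ang <- rng$runif(1, 0, pi)
    val <- rng$runif(1, 0.2, 0.6) * spec$rimIntensity
    tissue <- fillEllipse(matrix(0, n, n), ecy, ecx, ery, erx, ang, val)
    keep <- inner == 1 & tissue > 0
    acc[keep] <- pmax(acc[keep], tissue[keep])
  }
  ## mild smoothing softens staircase edges without destroying the rim
  acc <- smooth3x3(acc)
  new("ImageSlice", pixels = clamp01(acc), pixelSpacing = 1)
}

## Internal 3x3 binomial smoothing with edge replication.
smooth3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  k <- c(0.25, 0.5, 0.25)
  out <- matrix(0, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      out <- out + k[dy + 2] * k[dx + 2] *
        pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
  }
  out
}

## Internal: an isolated RNG that never touches the global .Random.seed.
localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  withState <- function(f) {
    function(...) {
      oldG <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(oldG)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", oldG, envir = globalenv())
      })
      f(...)
    }
  }
  list(runif = withState(stats::runif),
       rnorm = withState(stats::rnorm),
       sample = withState(base::sample),
       sampleInt = withState(function(n, k) base::sample.int(n, k)))
}

#' Generate a paired clean/corrupted phantom dataset
#'
#' Builds \code{n} phantom slices, corrupts each at the requested severities,
#' and splits them into disjoint train/test sets. Each corrupted entry stores
#' the motion events and the ground-truth line mask used to make it, so the
#' archive can be regenerated bit-exactly from its config snapshot.
#'
#' @param n number of phantom slices (>= 2).
#' @param spec base \code{\link{phantomSpec}}; each slice uses
#'   \code{seed + i - 1}.
#' @param split numeric (trainFrac, testFrac) summing to 1; both parts must
#'   be non-empty.
#' @param severities character subset of c("minor", "moderate", "heavy").
#' @param seed integer seed controlling corruption sampling.
#' @param centerExclusionFrac protected central PE band fraction.
#' @return a \linkS4class{PairedMotionData}.
#' @export
generateDataset <- function(n, spec = phantomSpec(),
                            split = c(0.8, 0.2),
                            severities = c("minor", "moderate", "heavy"),
                            seed = 1L, centerExclusionFrac = 0.08) {
  if (n < 2) stop("need at least 2 slices", call. = FALSE)
  if (length(split) != 2 || any(split <= 0) || abs(sum(split) - 1) > 1e-8)
    stop("split must be two positive fractions summing to 1", call. = FALSE)
  nTrain <- round(split[1] * n)
  if (nTrain < 1 || nTrain > n - 1)
    stop("degenerate split: each partition must be non-empty", call. = FALSE)
  severities <- match.arg(severities, several.ok = TRUE)

  clean <- lapply(seq_len(n), function(i) {
    s <- spec; s$seed <- spec$seed + i - 1L
    generatePhantom(s)
  })
  corrupted <- masks <- events <- stats::setNames(
    rep(list(vector("list", n)), length(severities)), severities)
  for (sv in severities) {
    preset <- severityPreset(sv, centerExclusionFrac = centerExclusionFrac)
    for (i in seq_len(n)) {
      evSeed <- seed * 10000L + i * 10L + match(sv, c("minor", "moderate", "heavy"))
      sim <- simulateMotion(clean[[i]], preset, seed = evSeed)
      corrupted[[sv]][[i]] <- sim$corrupted
      masks[[sv]][[i]] <- sim$mask
      events[[sv]][[i]] <- sim$events
    }
  }
  new("PairedMotionData", clean = clean, corrupted = corrupted,
      masks = masks, events = events,
      trainIdx = seq_len(nTrain), testIdx = seq.int(nTrain + 1L, n),
      config = list(n = n, spec = unclass(spec), split = split,
                    severities = severities, seed = seed,
                    centerExclusionFrac = centerExclusionFrac))
}
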