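# Internal helpers shared across modules.

## DC-centering shifts for matrices. fftCenter moves the (1,1) DC coefficient
## of an unshifted FFT to row floor(H/2)+1, col floor(W/2)+1; fftUncenter is
## its exact inverse for any (even or odd) size.
fftCenter <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq.int(floor(h / 2) + 1L, h), seq_len(floor(h / 2))),
    c(seq.int(floor(w / 2) + 1L, w), seq_len(floor(w / 2))), drop = FALSE]
}

fftUncenter <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq.int(ceiling(h / 2) + 1L, h), seq_len(ceiling(h / 2))),
    c(seq.int(ceiling(w / 2) + 1L, w), seq_len(ceiling(w / 2))), drop = FALSE]
}

## Row index of the DC coefficient in a DC-centered grid (1-based).
dcIndex <- function(n) floor(n / 2) + 1L

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

## Bilinear sampling of matrix `img` at fractional (row, col) coordinates.
## Coordinates are 1-based; samples outside the grid return `fill`.
## Vectorized over coordinate vectors of equal length.
bilinearSample <- function(img, r, c, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;  fc <- c - c0
  out <- numeric(length(r)) + fill
  ## contribution of each of the four neighbours, zero outside the grid
  acc <- numeric(length(r))
  for (dr in 0:1) {
    for (dc in 0:1) {
      rr <- r0 + dr; cc <- c0 + dc
      wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      idx <- (cc[ok] - 1) * h + rr[ok]
      acc[ok] <- acc[ok] + wgt[ok] * img[idx]
    }
  }
  ## a sample point with all four neighbours outside keeps `fill`
  inside <- r >= 0.5 - 1e-12 & r <= h + 0.5 + 1e-12 &
            c >= 0.5 - 1e-12 & c <= w + 0.5 + 1e-12
  out[inside] <- acc[inside]
  out
}

## 1D Gaussian kernel, normalized to sum 1.
gaussianKernel1d <- function(size, sigma) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

## Valid-mode separable 2D filtering: returns (H-size+1) x (W-size+1).
separableFilterValid <- function(img, k) {
  n <- length(k)
  h <- nrow(img); w <- ncol(img)
  B1 <- matrix(0, h - n + 1L, h)
  for (i in seq_len(h - n + 1L)) B1[i, i:(i + n - 1L)] <- k
  B2 <- matrix(0, w - n + 1L, w)
  for (i in seq_len(w - n + 1L)) B2[i, i:(i + n - 1L)] <- k
  B1 %*% img %*% t(B2)
}
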