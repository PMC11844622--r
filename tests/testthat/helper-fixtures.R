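# Shared fixtures and small oracles used across the test files.

## A reproducible random image slice (values in [0, 1]).
randomSlice <- function(n = 32, seed = 1) {
  set.seed(seed)
  imageSlice(matrix(runif(n * n), n, n))
}

## A small phantom (fast default for unit tests).
phantom64 <- function(seed = 1) generatePhantom(phantomSpec(size = 64, seed = seed))

## Dice overlap of two binary vectors (independent of the package's loss).
diceOverlap <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a * b) / (sum(a) + sum(b))
}

## Line indices covered by a list of MotionEvents (ignoring center exclusion).
eventLines <- function(events, height) {
  out <- integer(0)
  for (ev in events) {
    s <- ev@slabStart
    out <- union(out, seq.int(s, s + ev@slabWidth - 1L))
  }
  sort(out[out >= 1 & out <= height])
}
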