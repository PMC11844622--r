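test_that("sampled events respect the preset bounds and slab geometry", {
  pre <- severityPreset("minor")
  evs <- sampleEvents(pre, height = 64, seed = 1)
  expect_length(evs, 5)
  widths <- vapply(evs, function(e) e@slabWidth, 0L)
  expect_true(all(widths >= 3L & widths <= 7L))

  ## slabs pairwise disjoint and outside the protected center band
  lines <- unlist(lapply(evs, function(e)
    seq.int(e@slabStart, e@slabStart + e@slabWidth - 1L)))
  expect_false(any(duplicated(lines)))
  banned <- kmoco:::centerBand(64, pre@centerExclusionFrac)
  expect_length(intersect(lines, banned), 0)

  ## zero slabs -> empty list
  expect_length(sampleEvents(severityPreset("minor", nSlabs = 0), 64), 0)
})

test_that("motion parameter distribution matches the uniform bounds", {
  pre <- severityPreset("minor")
  thetas <- unlist(lapply(1:2000, function(s)
    vapply(sampleEvents(pre, 256, seed = s), function(e) e@thetaDeg, 0)))
  expect_length(thetas, 10000)
  expect_gte(min(thetas), -7)
  expect_lte(max(thetas), 7)
  se <- (14 / sqrt(12)) / sqrt(length(thetas))
  expect_lt(abs(mean(thetas)), 3 * se)
})

test_that("an infeasible grid is rejected with the required height", {
  expect_error(sampleEvents(severityPreset("heavy"), height = 32, seed = 1),
               "cannot host")
})

test_that("mask construction counts slab lines and honors the center band", {
  expect_identical(maskValues(buildMask(list(), 32)), numeric(32))

  evs <- list(motionEvent(1, 0, 0, slabStart = 2, slabWidth = 4),
              motionEvent(-2, 1, 1, slabStart = 25, slabWidth = 3))
  m <- buildMask(evs, 32, centerExclusionFrac = 0)
  expect_equal(sum(maskValues(m)), 7)

  ## an event overlapping the center band leaves those lines at 0
  dc <- floor(32 / 2) + 1L
  evC <- list(motionEvent(3, 0, 0, slabStart = dc - 1L, slabWidth = 3))
  mC <- buildMask(evC, 32, centerExclusionFrac = 0.1)
  banned <- kmoco:::centerBand(32, 0.1)
  expect_true(all(maskValues(mC)[banned] == 0))
})

test_that("k-space splicing is exact per line", {
  img <- phantom64(6)
  kGT <- toKSpace(img)

  ## empty event list: bit-exact passthrough
  out <- corruptKSpace(kGT, list())
  expect_identical(coeffs(out$kmotion), coeffs(kGT))

  ## zero-motion event: identity within 1e-10
  ev0 <- list(motionEvent(0, 0, 0, slabStart = 10, slabWidth = 4))
  out0 <- corruptKSpace(kGT, ev0)
  expect_lt(max(Mod(coeffs(out0$kmotion) - coeffs(kGT))), 1e-10)

  ## one slab at lines 10..13: spliced lines equal the transformed spectrum
  ## bit-exactly, neighbours equal the original bit-exactly
  ev <- list(motionEvent(5, 2, 0, slabStart = 10, slabWidth = 4))
  spl <- corruptKSpace(kGT, ev)
  kt <- kspaceRigid(kGT, 5, 2, 0)
  expect_identical(coeffs(spl$kmotion)[10:13, ], coeffs(kt)[10:13, ])
  expect_identical(coeffs(spl$kmotion)[c(9, 14), ], coeffs(kGT)[c(9, 14), ])
  expect_equal(maskValues(spl$mask)[10:13], rep(1, 4))
})

test_that("uncorrupted lines always stay bit-identical (data-consistency basis)", {
  img <- phantom64(7)
  kGT <- toKSpace(img)
  for (s in 1:5) {
    evs <- sampleEvents(severityPreset("moderate"), 64, seed = s)
    spl <- corruptKSpace(kGT, evs)
    keep <- which(maskValues(spl$mask) == 0)
    expect_identical(coeffs(spl$kmotion)[keep, ], coeffs(kGT)[keep, ])
  }
})

test_that("simulation is seeded, non-degenerate and mask-consistent", {
  img <- phantom64(8)
  a <- simulateMotion(img, severityPreset("minor"), seed = 42)
  b <- simulateMotion(img, severityPreset("minor"), seed = 42)
  expect_identical(pixels(a$corrupted), pixels(b$corrupted))

  ## corrupted differs from clean
  expect_gt(max(abs(pixels(a$corrupted) - pixels(img))), 1e-6)

  ## mask reconstructed from stored events equals the stored mask
  expect_identical(maskValues(buildMask(a$events, 64, 0.08)),
                   maskValues(a$mask))
})

## (Severity monotonicity of corrupted-image quality is asserted with the
## end-to-end pipeline properties in test-acceptance.R.)
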