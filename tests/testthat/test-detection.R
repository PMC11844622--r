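test_that("spatial averaging is a row-mean projection", {
  ## row of alternating 0/1 -> 0.5 for that line
  raw <- matrix(0, 4, 8)
  raw[2, ] <- rep(c(0, 1), 4)
  m <- spatialAverage(raw)
  expect_equal(maskValues(m), c(0, 0.5, 0, 0))

  ## already line-constant map: output equals any column (idempotence)
  rawC <- matrix(rep(c(0.2, 0.7, 0.1, 0.9), 6), 4, 6)
  expect_equal(maskValues(spatialAverage(rawC)), rawC[, 1])

  ## projection: averaging the broadcast average changes nothing
  m1 <- spatialAverage(raw)
  m2 <- spatialAverage(broadcastMask(m1, 8))
  expect_equal(maskValues(m2), maskValues(m1))

  ## all-zero raw -> all-zero mask
  expect_equal(maskValues(spatialAverage(matrix(0, 3, 3))), rep(0, 3))

  expect_error(spatialAverage(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("Dice loss matches hand-computed values", {
  ## worked example: MGT = [1,1,0,0], Mp = [1,0,0,0] -> 1 - 2/3 = 1/3
  expect_equal(diceLoss(c(1, 0, 0, 0), c(1, 1, 0, 0)), 1 / 3,
               tolerance = 1e-6)

  ## perfect overlap ~ 0; disjoint equal-size masks ~ 1
  m <- c(1, 1, 0, 0, 1)
  expect_lte(diceLoss(m, m), 1e-6)
  expect_gte(diceLoss(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1 - 1e-5)

  expect_error(diceLoss(c(1, 0), c(1, 0, 0)), "shapes differ")
})

test_that("BCE loss matches closed forms and the clipping contract", {
  gt <- c(1, 0, 1, 1, 0)
  ## uniform 0.5 prediction -> ln 2 per element
  expect_equal(bceLoss(rep(0.5, 5), gt), log(2), tolerance = 1e-12)
  ## perfect confident prediction: bounded by the clip
  expect_lt(bceLoss(gt, gt), 1e-5)
  ## perfectly wrong confident prediction -> -ln(clip) per element
  expect_equal(bceLoss(1 - gt, gt, clip = 1e-6), -log(1e-6),
               tolerance = 1e-9)
  expect_error(bceLoss(c(1, 0), c(1, 0, 0)), "shapes differ")
})

test_that("segmentation loss is Dice plus BCE", {
  mp <- c(0.9, 0.2, 0.6, 0.1)
  gt <- c(1, 0, 1, 0)
  expect_equal(segLoss(mp, gt), diceLoss(mp, gt) + bceLoss(mp, gt))
})

test_that("mask prediction is line-structured, bounded and peripherally excluded", {
  img <- phantom64(9)
  sim <- simulateMotion(img, severityPreset("minor"), seed = 2)
  model <- detectorModel(detectionConfig(), seed = 3)
  out <- detectMask(sim$kmotion, model)

  ## raw sigmoid map in [0, 1] even for an untrained network
  expect_true(all(out$raw >= 0 & out$raw <= 1))

  ## averaged mask equals the row means with the peripheral band zeroed:
  ## constant along the frequency axis by construction
  inc <- kmoco:::includedLines(64, model$cfg$peripheralFrac)
  expect_equal(maskValues(out$averaged)[inc], rowMeans(out$raw)[inc])
  expect_true(all(maskValues(out$averaged)[-inc] == 0))

  ## binarization at the configured threshold
  expect_equal(maskValues(out$binary),
               as.numeric(maskValues(out$averaged) >= 0.5))
})

test_that("indivisible input shapes are rejected with the required padding", {
  img <- imageSlice(matrix(runif(58 * 58), 58))  # 58 not divisible by 4
  model <- detectorModel(detectionConfig(depth = 2L))
  expect_error(detectMask(toKSpace(img), model), "58 x 58")
  expect_error(detectMask(toKSpace(img), model), "pad to 60 x 60")
})
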