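test_that("an untrained corrector is the identity on clean inputs", {
  img <- phantom64(10)
  model <- correctorModel(correctionConfig(), seed = 4)
  out <- correctSlice(img, model)
  expect_identical(dim(pixels(out)), dim(pixels(img)))
  expect_true(all(is.finite(pixels(out))))
  expect_true(all(pixels(out) >= 0 & pixels(out) <= 1))
  ## zero-initialized residual head: output matches input
  expect_lt(mean(abs(pixels(out) - pixels(img))), 1e-3)
})

test_that("incompatible shapes are rejected with the required padding", {
  img <- imageSlice(matrix(runif(58 * 58), 58))
  expect_error(correctSlice(img, correctorModel()), "pad to 60 x 60")
})

test_that("L1 loss matches closed forms and is symmetric", {
  a <- matrix(runif(64), 8)
  expect_equal(l1Loss(a, a), 0)
  expect_equal(l1Loss(a + 0.03, a), 0.03, tolerance = 1e-12)
  b <- matrix(runif(64), 8)
  expect_equal(l1Loss(a, b), l1Loss(b, a))
  expect_error(l1Loss(a, matrix(0, 4, 4)), "shapes differ")
})

test_that("perceptual loss vanishes at identity, is symmetric, and ranks noise above blur", {
  fe <- featureExtractor(seed = 5)
  a <- pixels(phantom64(11))
  expect_lt(lpipsLoss(a, a, fe), 1e-8)
  b <- a + 0.01
  expect_equal(lpipsLoss(a, b, fe), lpipsLoss(b, a, fe), tolerance = 1e-12)

  ## at matched L2 distortion, high-frequency noise is perceptually farther
  ## than a smoothing of the same energy
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    noise <- matrix(rnorm(length(a)), nrow(a))
    smoothDiff <- kmoco:::smooth3x3(a) - a
    d <- sqrt(sum(smoothDiff^2))
    noisy <- a + noise * d / sqrt(sum(noise^2))
    blurred <- a + smoothDiff
    expect_equal(sum((noisy - a)^2), sum((blurred - a)^2), tolerance = 1e-9)
    if (lpipsLoss(noisy, a, fe) > lpipsLoss(blurred, a, fe)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("data-consistency loss depends only on masked lines", {
  img <- phantom64(12)
  x <- pixels(img)
  n <- nrow(x)
  expect_equal(dcLoss(x, x, lineMask(rep(1, n))), 0)
  ## all-zero mask ignores arbitrary differences
  y <- matrix(runif(n * n), n)
  expect_equal(dcLoss(y, x, lineMask(numeric(n))), 0)

  ## construct a difference supported on chosen centered k-space lines; a
  ## conjugate-symmetric pair keeps the perturbed image real
  dc <- floor(n / 2) + 1L
  lines <- c(dc - 10L, dc + 10L)
  k <- matrix(complex(real = 0), n, n)
  k[lines[1], dc + 3L] <- 2 + 1i
  k[lines[2], dc - 3L] <- Conj(k[lines[1], dc + 3L])
  delta <- pixels(fromKSpace(new("KSpaceSlice", coeffs = k,
                                 pixelSpacing = 1)))
  x2 <- x + delta

  mOff <- numeric(n); mOff[dc - 20L] <- 1       # mask away from the support
  expect_lt(dcLoss(x2, x, lineMask(mOff)), 1e-20)
  mOn <- numeric(n); mOn[lines] <- 1            # mask on the support
  expect_gt(dcLoss(x2, x, lineMask(mOn)), 1e-8)
})

test_that("the composite loss combines terms linearly with the lambda weights", {
  ## worked arithmetic: 10*0.1 + 0.5*0.2 + 100*0.01 = 2.1
  out <- combineLossTerms(0.1, 0.2, 0.01, correctionConfig())
  expect_equal(out$total, 2.1, tolerance = 1e-12)

  img <- phantom64(13)
  sim <- simulateMotion(img, severityPreset("minor"), seed = 3)
  fe <- featureExtractor()
  full <- totalLoss(sim$corrupted, img, sim$mask, correctionConfig(), fe)
  expect_equal(full$total,
               10 * full$l1 + 0.5 * full$lpips + 100 * full$dc)

  ## identical images: zero total and zero per term
  z <- totalLoss(img, img, sim$mask, correctionConfig(), fe)
  expect_lt(z$total, 1e-8)
  expect_equal(z$l1, 0)

  ## lambdaL = lambdaD = 0 reduces exactly to 10 * L1
  cfgL1 <- correctionConfig(lambdaL = 0, lambdaD = 0)
  only <- totalLoss(sim$corrupted, img, sim$mask, cfgL1, fe)
  expect_equal(only$total, 10 * l1Loss(sim$corrupted, img))

  ## linearity in each lambda
  cfg2 <- correctionConfig(lambdaR = 20, lambdaL = 1, lambdaD = 200)
  dbl <- totalLoss(sim$corrupted, img, sim$mask, cfg2, fe)
  expect_equal(dbl$total, 2 * full$total, tolerance = 1e-10)
})
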