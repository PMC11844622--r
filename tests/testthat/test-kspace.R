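test_that("forward transform follows the orthonormal DC-centered convention", {
  ## linearity: zero image -> zero spectrum
  z <- toKSpace(imageSlice(matrix(0, 64, 64) + 0))
  expect_true(all(Mod(coeffs(z)) == 0))

  ## constant image -> single nonzero coefficient at the centered origin
  k <- coeffs(toKSpace(imageSlice(matrix(0.4, 32, 32))))
  dc <- floor(32 / 2) + 1L
  expect_gt(Mod(k[dc, dc]), 0)
  k[dc, dc] <- 0
  expect_lt(max(Mod(k)), 1e-12)

  ## Parseval under ortho normalization, 50 random images
  for (s in 1:50) {
    img <- randomSlice(16, seed = s)
    expect_lt(abs(sum(pixels(img)^2) - sum(Mod(coeffs(toKSpace(img)))^2)),
              1e-8)
  }
})

test_that("non-finite input is rejected with an informative message", {
  m <- matrix(0.5, 16, 16)
  m[3, 4] <- NaN
  img <- imageSlice(matrix(0.5, 16, 16))
  methods::slot(img, "pixels", check = FALSE) <- m  # bypass the class guard
  expect_error(toKSpace(img), "non-finite")
})

test_that("inverse transform round-trips and reconstructs DC-only spectra", {
  img <- phantom64(2)
  back <- fromKSpace(toKSpace(img))
  expect_lt(max(abs(pixels(back) - pixels(img))), 1e-10)
  expect_lt(back@imagResidue, 1e-10)

  ## DC-only spectrum of amplitude a -> constant image a / sqrt(N)
  n <- 16L
  k <- matrix(complex(real = 0), n, n)
  dc <- floor(n / 2) + 1L
  k[dc, dc] <- 5 + 0i
  const <- pixels(fromKSpace(new("KSpaceSlice", coeffs = k, pixelSpacing = 1)))
  expect_lt(diff(range(const)), 1e-12)
  expect_equal(const[1, 1], 5 / n, tolerance = 1e-12)
})

test_that("corrupted spectra reconstruct to finite magnitude images", {
  img <- phantom64(3)
  sim <- simulateMotion(img, severityPreset("moderate"), seed = 4)
  expect_true(all(is.finite(pixels(sim$corrupted))))
  expect_true(all(pixels(sim$corrupted) >= 0))  # magnitude image
  expect_gt(sim$corrupted@imagResidue, 1e-6)    # asymmetric spectrum reported
})

test_that("rigid image transform honors identity, symmetry and inversion", {
  img <- phantom64(1)
  ## exact identity (bit-equal)
  expect_identical(pixels(rigidTransformImage(img, 0, 0, 0)), pixels(img))

  ## 90-degree rotation leaves a centered axis-aligned square invariant
  m <- matrix(0, 64, 64)
  m[25:40, 25:40] <- 1
  sq <- imageSlice(m)
  rot <- rigidTransformImage(sq, 90, 0, 0)
  expect_lt(max(abs(pixels(rot) - m)), 1e-6)

  ## approximate inverse: forward then reversed-order inverse, interior MAE
  fwd <- rigidTransformImage(img, 7, 5, -5)
  inv <- rigidTransformImage(fwd, -7, -5, 5, order = "rotate_translate")
  interior <- 9:56
  mae <- mean(abs(pixels(inv)[interior, interior] -
                  pixels(img)[interior, interior]))
  expect_lt(mae, 0.02)
})

test_that("translations in mm scale with pixel spacing", {
  m <- matrix(0, 16, 16)
  m[8, 8] <- 1
  img2 <- imageSlice(m, pixelSpacing = 2)   # 2 mm per pixel
  out <- rigidTransformImage(img2, 0, 4, 0) # 4 mm = 2 px along columns
  expect_equal(pixels(out)[8, 10], 1, tolerance = 1e-12)
})

test_that("k-space rigid operator is identity at zero motion and obeys the shift theorem", {
  img <- phantom64(4)
  ks <- toKSpace(img)
  expect_lt(max(Mod(coeffs(kspaceRigid(ks, 0, 0, 0)) - coeffs(ks))), 1e-10)

  ## pure translation: analytic phase ramp on the central half of k-space
  tx <- 3; ty <- -2
  kt <- kspaceRigid(ks, 0, tx, ty)
  n <- 64L
  f <- seq_len(n) - (floor(n / 2) + 1L)
  ramp <- exp(-2i * pi * (outer(f * ty, rep(0, n), "+") +
                          outer(rep(0, n), f * tx, "+")) / n)
  pred <- coeffs(ks) * ramp
  cen <- (n / 4 + 1):(3 * n / 4)
  got <- coeffs(kt)[cen, cen]
  want <- pred[cen, cen]
  big <- Mod(want) > 1e-9
  expect_lt(max(abs(Mod(got)[big] / Mod(want)[big] - 1)), 0.02)
  dphi <- Arg(got[big] / want[big])
  expect_lt(max(abs(dphi)), 0.05)

  ## zero fill can only remove energy
  kr <- kspaceRigid(ks, 7, 5, -5)
  expect_lte(sum(Mod(coeffs(kr))^2), sum(Mod(coeffs(ks))^2) + 1e-6)
})
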