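## Training tests run at miniature scale (tiny networks, few steps): they
## verify the mechanics — seeding, logging, checkpointing, scenario wiring —
## not learning quality, which the end-to-end properties cover.

tinyArchive <- function() {
  generateDataset(4, phantomSpec(size = 32, seed = 9), split = c(0.5, 0.5),
                  severities = "minor", seed = 17)
}

tinyConfigs <- function() {
  list(train = trainConfig(steps = 3L, batchSize = 2L, seed = 5L),
       det = detectionConfig(depth = 1L, width = 4L),
       cor = correctionConfig(depth = 1L, width = 4L, windowSize = 4L,
                              nHeads = 2L, nSwin = 1L),
       fe = featureExtractor(widths = c(4L, 8L)))
}

test_that("training is reproducible and logs per-term losses", {
  arch <- tinyArchive()
  cfg <- tinyConfigs()
  a <- trainModels(arch, "minor", cfg$train, cfg$det, cfg$cor, cfg$fe)
  b <- trainModels(arch, "minor", cfg$train, cfg$det, cfg$cor, cfg$fe)
  expect_identical(a$losses, b$losses)             # bit-identical curves
  expect_identical(a$detector$params, b$detector$params)
  expect_named(a$losses, c("step", "lseg", "lcor", "l1", "lpips", "dc"))
  expect_equal(nrow(a$losses), 3)
  expect_true(all(is.finite(as.matrix(a$losses))))
  ## composite loss equals its logged breakdown
  expect_equal(a$losses$lcor,
               10 * a$losses$l1 + 0.5 * a$losses$lpips + 100 * a$losses$dc,
               tolerance = 1e-10)
})

test_that("training validates its inputs", {
  arch <- tinyArchive()
  cfg <- tinyConfigs()
  empty <- arch
  methods::slot(empty, "trainIdx", check = FALSE) <- integer(0)
  expect_error(trainModels(empty, "minor", cfg$train, cfg$det, cfg$cor),
               "empty training set")
  expect_error(trainModels(arch, "heavy", cfg$train, cfg$det, cfg$cor),
               "not stored")
})

test_that("training writes checkpoints that reload bit-exactly", {
  arch <- tinyArchive()
  cfg <- tinyConfigs()
  dir <- tempfile()
  dir.create(dir)
  fit <- trainModels(arch, "minor", cfg$train, cfg$det, cfg$cor, cfg$fe,
                     checkpointDir = dir)
  final <- file.path(dir, "ckpt_final.rds")
  expect_true(file.exists(final))
  back <- loadCheckpoint(final)
  expect_identical(back$corrector$params, fit$corrector$params)
})

test_that("the paper-scale configuration carries the reference settings", {
  tc <- trainConfig("paper")
  expect_equal(tc$batchSize, 32L)
  expect_equal(tc$lr, 2e-4)
  expect_equal(tc$epochs, 25L)
  expect_equal(tc$adamBetas, c(0.9, 0.999))
})

test_that("ablation scenarios share data and wire the lambda switches", {
  arch <- tinyArchive()
  cfg <- tinyConfigs()
  tab <- runAblation(arch, "minor", scenarios = c("L1", "full"),
                     seeds = 5L, trainCfg = cfg$train, detCfg = cfg$det,
                     corCfg = cfg$cor, fe = cfg$fe)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$scenario, c("L1", "full"))
  expect_true(all(tab$nmse >= 0))
  expect_true(all(tab$psnrLow <= tab$psnr & tab$psnr <= tab$psnrHigh))

  ## the L1 scenario trains with lambdaL = lambdaD = 0: its logged
  ## correction loss must equal lambdaR * L1 exactly
  cfgL1 <- cfg$cor
  cfgL1$lambdaL <- 0; cfgL1$lambdaD <- 0
  fit <- trainModels(arch, "minor", cfg$train, cfg$det, cfgL1, cfg$fe)
  expect_equal(fit$losses$lcor, 10 * fit$losses$l1, tolerance = 1e-12)
  expect_true(all(fit$losses$lpips == 0) && all(fit$losses$dc == 0))
})

test_that("the DC mask never reads the ground truth in predicted mode", {
  arch <- tinyArchive()
  cfg <- tinyConfigs()
  ## corrupting the stored ground-truth masks changes the detector's loss
  ## but must leave the corrector's DC term untouched when dcMask=predicted
  broken <- arch
  scrambled <- lapply(broken@masks$minor, function(m)
    lineMask(rev(maskValues(m)), binary = TRUE))
  methods::slot(broken, "masks", check = FALSE) <- list(minor = scrambled)
  a <- trainModels(arch, "minor", cfg$train, cfg$det, cfg$cor, cfg$fe)
  b <- trainModels(broken, "minor", cfg$train, cfg$det, cfg$cor, cfg$fe)
  expect_equal(a$losses$dc[1], b$losses$dc[1], tolerance = 1e-12)
})
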