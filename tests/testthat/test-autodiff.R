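# Every differentiation rule in the engine is checked against central
# finite differences on small random problems.

fdCheck <- function(buildLoss, params, probes = 3L, eps = 1e-6, tol = 1e-4,
                    seed = 1) {
  set.seed(seed)
  g <- buildLoss(params)
  kmoco:::agBackward(g$tape, g$loss)
  grads <- kmoco:::leafGrads(g$leaves)
  for (nm in names(params)) {
    for (k in seq_len(probes)) {
      i <- sample(length(params[[nm]]), 1)
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- buildLoss(p2)$loss$val
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- buildLoss(p2)$loss$val
      num <- (up - dn) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), tol,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
}

test_that("convolution, pooling and upsampling gradients match finite differences", {
  set.seed(11)
  params <- list(x = array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                 w = matrix(rnorm(27 * 4, 0, 0.3), 27, 4),
                 b = rnorm(4),
                 w1 = matrix(rnorm(4 * 2, 0, 0.3), 4, 2),
                 b1 = rnorm(2))
  fdCheck(function(p) {
    tape <- kmoco:::agTape()
    lf <- kmoco:::leafify(tape, p)
    h <- kmoco:::agConv2d(tape, lf$leaves$x, lf$leaves$w, lf$leaves$b)
    h <- kmoco:::agRelu(tape, h)
    h <- kmoco:::agAvgPool2(tape, h)
    h <- kmoco:::agUpsample2(tape, h)
    h <- kmoco:::agConv2d(tape, h, lf$leaves$w1, lf$leaves$b1, k = 1L)
    loss <- kmoco:::agMseLoss(tape, h, array(0.1, c(8, 8, 2)))
    list(tape = tape, loss = loss, leaves = lf$leaves)
  }, params)
})

test_that("layer norm, linear and window attention gradients match finite differences", {
  set.seed(12)
  C <- 6L
  params <- list(x = matrix(rnorm(32 * C), 32, C),
                 g = runif(C, 0.5, 1.5), bta = rnorm(C),
                 wqkv = matrix(rnorm(C * 3 * C, 0, 0.3), C, 3 * C),
                 bqkv = rnorm(3 * C),
                 wo = matrix(rnorm(C * C, 0, 0.3), C, C), bo = rnorm(C))
  fdCheck(function(p) {
    tape <- kmoco:::agTape()
    lf <- kmoco:::leafify(tape, p)
    h <- kmoco:::agLayerNorm(tape, lf$leaves$x, lf$leaves$g, lf$leaves$bta)
    h <- kmoco:::agWindowAttention(tape, h, lf$leaves$wqkv, lf$leaves$bqkv,
                                   lf$leaves$wo, lf$leaves$bo,
                                   nHeads = 2L, tokens = 16L)
    loss <- kmoco:::agMseLoss(tape, h, matrix(0, 32, C))
    list(tape = tape, loss = loss, leaves = lf$leaves)
  }, params, tol = 1e-3)
})

test_that("segmentation and reconstruction loss gradients match finite differences", {
  set.seed(13)
  gt <- as.numeric(runif(20) > 0.6)
  target <- matrix(runif(64), 8, 8)
  maskVec <- as.numeric(runif(8) > 0.5)
  params <- list(v = runif(20, 0.05, 0.95),
                 img = array(runif(64), c(8, 8, 1)))
  fdCheck(function(p) {
    tape <- kmoco:::agTape()
    lf <- kmoco:::leafify(tape, p)
    l1 <- kmoco:::agDiceLoss(tape, lf$leaves$v, gt)
    l2 <- kmoco:::agBceLoss(tape, lf$leaves$v, gt)
    l3 <- kmoco:::agMseLoss(tape, lf$leaves$img, array(target, c(8, 8, 1)))
    l4 <- kmoco:::agDcLoss(tape, lf$leaves$img, target, maskVec)
    loss <- kmoco:::agWeightedSum(tape, list(l1, l2, l3, l4),
                                  c(1, 1, 2, 3))
    list(tape = tape, loss = loss, leaves = lf$leaves)
  }, params)
})

test_that("gather, concat and row-mean gradients match finite differences", {
  set.seed(14)
  params <- list(a = array(rnorm(6 * 6 * 2), c(6, 6, 2)),
                 b = array(rnorm(6 * 6 * 1), c(6, 6, 1)))
  idx <- sample(36)
  fdCheck(function(p) {
    tape <- kmoco:::agTape()
    lf <- kmoco:::leafify(tape, p)
    cc <- kmoco:::agConcatC(tape, lf$leaves$a, lf$leaves$b)
    m <- kmoco:::agAsMatrix(tape, cc)
    s <- kmoco:::agSigmoid(tape, m)
    gth <- kmoco:::agGatherRows(tape, s, idx)
    rm <- kmoco:::agRowMean(tape, kmoco:::agMulConst(tape, gth, 1))
    sub <- kmoco:::agGatherVec(tape, rm, c(2, 5, 6))
    loss <- kmoco:::agBceLoss(tape, sub, c(1, 0, 1))
    list(tape = tape, loss = loss, leaves = lf$leaves)
  }, params)
})

test_that("the data-consistency gradient only sees masked lines", {
  set.seed(15)
  target <- matrix(runif(64), 8, 8)
  maskVec <- c(0, 1, 1, 0, 0, 0, 0, 0)
  tape <- kmoco:::agTape()
  x <- kmoco:::agLeaf(tape, array(runif(64), c(8, 8, 1)))
  loss <- kmoco:::agDcLoss(tape, x, target, maskVec)
  kmoco:::agBackward(tape, loss)
  expect_true(all(is.finite(x$grad)))
  ## zero mask -> zero loss and zero gradient
  tape2 <- kmoco:::agTape()
  x2 <- kmoco:::agLeaf(tape2, array(runif(64), c(8, 8, 1)))
  loss2 <- kmoco:::agDcLoss(tape2, x2, target, numeric(8))
  kmoco:::agBackward(tape2, loss2)
  expect_equal(loss2$val, 0)
  expect_true(all(x2$grad == 0))
})
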