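# Joint training of the detection and correction networks.
#
# "Trained simultaneously" is implemented as alternating steps on the shared
# batch: one Adam update of the detector under the Dice+BCE loss, then one
# Adam update of the corrector under the composite loss, with the predicted
# mask detached (no gradient flows from the data-consistency term into the
# detector). Everything is seeded; with one BLAS thread two runs with the
# same seed produce bit-identical loss curves.

#' Training configuration
#'
#' The "paper" preset carries the reference optimization settings (batch 32,
#' learning rate 2e-4, 25 epochs, Adam with betas 0.9/0.999). The "desk"
#' preset is the CPU-scale configuration used throughout the test harness:
#' batch 4, learning rate 2.5e-3, 200 joint steps.
#'
#' @param preset "desk" (default) or "paper".
#' @param batchSize,lr,epochs,steps,adamBetas,seed overrides. \code{steps}
#'   (total joint steps) takes precedence over \code{epochs} when set.
#' @param lrCorrector learning rate for the correction network when it
#'   differs from the detector's (the desk preset uses 2.5e-3 / 2e-3: the
#'   shortened schedule favours a faster detector, while the corrector
#'   destabilizes above 2e-3).
#' @param deterministic keep full bit-reproducibility (default TRUE).
#' @return list of class "trainConfig".
#' @export
trainConfig <- function(preset = c("desk", "paper"), batchSize = NULL,
                        lr = NULL, lrCorrector = NULL, epochs = NULL,
                        steps = NULL, adamBetas = c(0.9, 0.999), seed = 7L,
                        deterministic = TRUE) {
  preset <- match.arg(preset)
  def <- if (preset == "paper")
    list(batchSize = 32L, lr = 2e-4, lrCor = 2e-4, epochs = 25L,
         steps = NULL)
  else
    list(batchSize = 4L, lr = 2.5e-3, lrCor = 2e-3, epochs = NULL,
         steps = 200L)
  structure(list(
    preset = preset,
    batchSize = as.integer(batchSize %||% def$batchSize),
    lr = lr %||% def$lr,
    lrCorrector = lrCorrector %||% (if (is.null(lr)) def$lrCor else lr),
    epochs = if (!is.null(epochs %||% def$epochs))
      as.integer(epochs %||% def$epochs) else NULL,
    steps = if (!is.null(steps %||% def$steps))
      as.integer(steps %||% def$steps) else NULL,
    adamBetas = adamBetas, seed = as.integer(seed),
    deterministic = isTRUE(deterministic)), class = "trainConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Precompute per-sample training tensors from an archive (one severity).
prepareSamples <- function(archive, severity, idx, detCfg) {
  lapply(idx, function(i) {
    clean <- archive@clean[[i]]
    events <- archive@events[[severity]][[i]]
    cx <- archive@config$centerExclusionFrac %||% 0.08
    kGT <- toKSpace(clean)
    spl <- corruptKSpace(kGT, events, cx)
    corrupted <- archive@corrupted[[severity]][[i]]
    list(cleanPx = clean@pixels,
         corruptedArr = array(corrupted@pixels,
                              c(dim(corrupted@pixels), 1L)),
         detInput = detectionInput(spl$kmotion, detCfg$inputRepr),
         gtMask = archive@masks[[severity]][[i]]@values)
  })
}

## One detector forward/loss on a prepared sample; returns loss node, tape,
## leaves and the averaged prediction values.
detectorLossGraph <- function(sample, params, detCfg) {
  tape <- agTape()
  lf <- leafify(tape, params)
  raw <- detectorForward(tape, sample$detInput, lf$leaves)
  avg <- agRowMean(tape, raw)
  h <- length(sample$gtMask)
  inc <- includedLines(h, detCfg$peripheralFrac)
  mpIn <- agGatherVec(tape, avg, inc)
  gtIn <- sample$gtMask[inc]
  loss <- agWeightedSum(tape,
                        list(agDiceLoss(tape, mpIn, gtIn),
                             agBceLoss(tape, mpIn, gtIn)), c(1, 1))
  avgFull <- avg$val
  avgFull[setdiff(seq_len(h), inc)] <- 0
  list(tape = tape, leaves = lf$leaves, loss = loss, averaged = avgFull)
}

## One corrector forward/loss on a prepared sample. maskVec: per-line DC
## mask values (already detached).
correctorLossGraph <- function(sample, params, corCfg, feLeafParams,
                               maskVec) {
  tape <- agTape()
  lf <- leafify(tape, params)
  out <- correctorForward(tape, sample$corruptedArr, lf$leaves, corCfg)
  terms <- list(agL1Loss(tape, out, array(sample$cleanPx,
                                          dim(sample$corruptedArr))))
  coefs <- corCfg$lambdaR
  if (corCfg$lambdaL != 0) {
    felf <- leafify(tape, feLeafParams)
    fa <- extractorForward(tape, out, felf$leaves)
    target <- agConst(tape, array(sample$cleanPx,
                                  dim(sample$corruptedArr)))
    fb <- extractorForward(tape, target, felf$leaves)
    lpNodes <- lapply(seq_along(fa), function(i)
      agMseBetween(tape, fa[[i]], fb[[i]]))
    lp <- agWeightedSum(tape, lpNodes, rep(1, length(lpNodes)))
    terms <- c(terms, list(lp)); coefs <- c(coefs, corCfg$lambdaL)
  }
  if (corCfg$lambdaD != 0) {
    dc <- agDcLoss(tape, out, sample$cleanPx, maskVec)
    terms <- c(terms, list(dc)); coefs <- c(coefs, corCfg$lambdaD)
  }
  loss <- agWeightedSum(tape, terms, coefs)
  list(tape = tape, leaves = lf$leaves, loss = loss,
       terms = vapply(terms, function(t) t$val, 0), coefs = coefs)
}

## Sum two nested gradient lists (handles NULLs).
gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- lapply(names(a), function(nm) gradAdd(a[[nm]], b[[nm]]))
    names(out) <- names(a)
    out
  } else a + b
}

gradScale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) lapply(g, gradScale, s = s) else g * s
}

#' Train the detection and correction networks jointly
#'
#' @param archive a \linkS4class{PairedMotionData}.
#' @param severity which stored severity to train on.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param detCfg a \code{\link{detectionConfig}}.
#' @param corCfg a \code{\link{correctionConfig}}.
#' @param fe a \code{\link{featureExtractor}} for the perceptual loss.
#' @param checkpointDir optional directory; a checkpoint is written after
#'   every epoch-equivalent (and at the end). A non-finite loss aborts the
#'   run and the last good checkpoint is returned.
#' @param verbose print a progress line every 25 steps.
#' @return list of class "trainedModels": \code{detector},
#'   \code{corrector}, \code{losses} (one row per step: lseg, lcor and the
#'   per-term breakdown), and the configs.
#' @export
trainModels <- function(archive, severity = "moderate",
                        trainCfg = trainConfig(),
                        detCfg = detectionConfig(),
                        corCfg = correctionConfig(),
                        fe = featureExtractor(),
                        checkpointDir = NULL, verbose = FALSE) {
  stopifnot(is(archive, "PairedMotionData"))
  idx <- archive@trainIdx
  if (length(idx) == 0) stop("empty training set", call. = FALSE)
  if (!severity %in% names(archive@corrupted))
    stop(sprintf("severity '%s' not stored in archive", severity),
         call. = FALSE)
  samples <- prepareSamples(archive, severity, idx, detCfg)
  h <- dim(samples[[1]]$detInput)[1]; w <- dim(samples[[1]]$detInput)[2]
  checkDivisible(h, w, detCfg$depth, "detection U-net")
  checkDivisible(h, w, corCfg$depth, "correction U-net")

  det <- detectorModel(detCfg, seed = trainCfg$seed)
  cor <- correctorModel(corCfg, seed = trainCfg$seed + 1L)
  detState <- adamInit(det$params)
  corState <- adamInit(cor$params)

  nSteps <- trainCfg$steps %||%
    (trainCfg$epochs * ceiling(length(samples) / trainCfg$batchSize))
  rng <- localRNG(trainCfg$seed * 131L + 17L)
  b1 <- trainCfg$adamBetas[1]; b2 <- trainCfg$adamBetas[2]
  inc <- includedLines(h, detCfg$peripheralFrac)

  log <- matrix(NA_real_, nSteps, 5L,
                dimnames = list(NULL, c("lseg", "lcor", "l1", "lpips", "dc")))
  lastGood <- list(det = det$params, cor = cor$params)
  stepsPerEpoch <- max(1L, ceiling(length(samples) / trainCfg$batchSize))

  for (step in seq_len(nSteps)) {
    bidx <- rng$sample(length(samples), min(trainCfg$batchSize,
                                            length(samples)))
    ## --- detector update ---
    dGrads <- NULL; lsegSum <- 0
    masks <- vector("list", length(bidx))
    for (j in seq_along(bidx)) {
      s <- samples[[bidx[j]]]
      g <- detectorLossGraph(s, det$params, detCfg)
      agBackward(g$tape, g$loss)
      dGrads <- gradAdd(dGrads, leafGrads(g$leaves))
      lsegSum <- lsegSum + g$loss$val
      masks[[j]] <- as.numeric(g$averaged >= detCfg$threshold)
    }
    dGrads <- gradScale(dGrads, 1 / length(bidx))
    up <- adamStep(det$params, dGrads, detState, trainCfg$lr, b1, b2)
    det$params <- up$params; detState <- up$state

    ## --- corrector update ---
    cGrads <- NULL; lcorSum <- 0; termSum <- c(l1 = 0, lpips = 0, dc = 0)
    for (j in seq_along(bidx)) {
      s <- samples[[bidx[j]]]
      maskVec <- if (corCfg$dcMask == "ground_truth") s$gtMask
                 else masks[[j]]
      g <- correctorLossGraph(s, cor$params, corCfg, fe$params, maskVec)
      agBackward(g$tape, g$loss)
      cGrads <- gradAdd(cGrads, leafGrads(g$leaves))
      lcorSum <- lcorSum + g$loss$val
      termSum["l1"] <- termSum["l1"] + g$terms[1]
      k <- 2L
      if (corCfg$lambdaL != 0) {
        termSum["lpips"] <- termSum["lpips"] + g$terms[k]; k <- k + 1L
      }
      if (corCfg$lambdaD != 0) termSum["dc"] <- termSum["dc"] + g$terms[k]
    }
    cGrads <- gradScale(cGrads, 1 / length(bidx))
    up <- adamStep(cor$params, cGrads, corState,
                   trainCfg$lrCorrector %||% trainCfg$lr, b1, b2)
    cor$params <- up$params; corState <- up$state

    nb <- length(bidx)
    log[step, ] <- c(lsegSum, lcorSum, termSum["l1"], termSum["lpips"],
                     termSum["dc"]) / nb
    if (!all(is.finite(log[step, c("lseg", "lcor")]))) {
      warning(sprintf("non-finite loss at step %d; keeping last checkpoint",
                      step))
      det$params <- lastGood$det
      cor$params <- lastGood$cor
      log <- log[seq_len(step), , drop = FALSE]
      break
    }
    lastGood <- list(det = det$params, cor = cor$params)
    if (!is.null(checkpointDir) && step %% stepsPerEpoch == 0L) {
      saveCheckpoint(list(detector = det, corrector = cor),
                     file.path(checkpointDir,
                               sprintf("ckpt_step%04d.rds", step)))
    }
    if (verbose && step %% 25L == 0L)
      message(sprintf("step %4d  lseg %.4f  lcor %.4f", step,
                      log[step, "lseg"], log[step, "lcor"]))
  }
  out <- structure(list(detector = det, corrector = cor,
                        losses = as.data.frame(cbind(step = seq_len(nrow(log)),
                                                     log)),
                        trainConfig = trainCfg, severity = severity),
                   class = "trainedModels")
  if (!is.null(checkpointDir))
    saveCheckpoint(list(detector = det, corrector = cor),
                   file.path(checkpointDir, "ckpt_final.rds"))
  out
}

#' Save / load model checkpoints
#'
#' Checkpoints round-trip bit-exactly (plain R serialization of the
#' parameter arrays).
#'
#' @param models list with detector/corrector models (as produced by
#'   \code{\link{trainModels}}).
#' @param path file path.
#' @return \code{loadCheckpoint} returns the models list.
#' @export
saveCheckpoint <- function(models, path) {
  saveRDS(models, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint '%s' does not exist", path), call. = FALSE)
  readRDS(path)
}

#' Loss-ablation study at one severity
#'
#' Trains the three loss scenarios — L1 only, L1 + data consistency, and the
#' full composite loss — on identical data and matched seeds, then evaluates
#' each on the archive's held-out slices. Scenario "L1" sets lambdaL and
#' lambdaD to 0; "L1+dc" sets lambdaL to 0.
#'
#' @param archive a \linkS4class{PairedMotionData}.
#' @param severity severity level to train/evaluate on.
#' @param scenarios subset of c("L1", "L1+dc", "full").
#' @param seeds integer vector of training seeds (one run per seed).
#' @param trainCfg,detCfg,corCfg,fe shared configuration.
#' @return data.frame with one row per scenario x seed: mean PSNR/SSIM/NMSE
#'   on the held-out slices plus bootstrap CIs for PSNR.
#' @export
runAblation <- function(archive, severity = "heavy",
                        scenarios = c("L1", "L1+dc", "full"),
                        seeds = c(7L, 8L, 9L),
                        trainCfg = trainConfig(),
                        detCfg = detectionConfig(),
                        corCfg = correctionConfig(),
                        fe = featureExtractor()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  testIdx <- archive@testIdx
  rows <- list()
  for (sc in scenarios) {
    cfg <- corCfg
    if (sc == "L1") { cfg$lambdaL <- 0; cfg$lambdaD <- 0 }
    if (sc == "L1+dc") cfg$lambdaL <- 0
    for (sd in seeds) {
      tc <- trainCfg; tc$seed <- as.integer(sd)
      fit <- trainModels(archive, severity, tc, detCfg, cfg, fe)
      ps <- ss <- nm <- numeric(length(testIdx))
      for (k in seq_along(testIdx)) {
        i <- testIdx[k]
        xc <- archive@corrupted[[severity]][[i]]
        xg <- archive@clean[[i]]
        xhat <- correctSlice(xc, fit$corrector)
        ps[k] <- psnr(xhat, xg)
        ss[k] <- ssim(xhat, xg)
        nm[k] <- nmse(xhat, xg)
      }
      ci <- if (length(ps) >= 2) bootstrapCI(ps, seed = sd)
            else c(ps, ps)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, seed = sd, severity = severity,
        psnr = mean(ps), psnrLow = ci[1], psnrHigh = ci[2],
        ssim = mean(ss), nmse = mean(nm))
    }
  }
  do.call(rbind, rows)
}
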