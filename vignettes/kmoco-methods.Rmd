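---
title: "Physics-informed simulation, detection and correction of rigid-motion artifacts in k-space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed simulation, detection and correction of rigid-motion artifacts in k-space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmoco)
```

## The physical model

A 2D Cartesian MR acquisition samples the Fourier transform of the object
one phase-encoding (PE) line at a time. When the head moves abruptly between
two lines — faster than the PE sampling rate but slower than the readout —
every line acquired after the movement measures the Fourier transform of a
rigidly transformed object. The corrupted spectrum is therefore a splice:

```
k_motion = (1 - M) * k_clean  +  M * T_Theta(k_clean)
```

where `M` is a binary mask over PE lines and `T_Theta = F o R_theta o T_(tx,ty)
o F^-1` applies an in-plane rotation and translation in image space between
an inverse and a forward Fourier transform. `kmoco` implements this splice
exactly: lines outside `M` are bit-identical to the clean spectrum. That
exactness is the physical basis for the k-space data-consistency loss used
during correction, and it is asserted bit-for-bit in the test suite.

Conventions, fixed package-wide and never per-call:

* orthonormal FFT (Parseval holds with unit constant);
* k-space is DC-centered wherever it is visible;
* phase encoding runs along matrix rows;
* rotations are about the geometric image center, interpolation is bilinear
  with zero fill, translations are specified in mm and converted through the
  slice's `pixelSpacing` (fixtures use 1 mm/px, so ±5 mm means ±5 px);
* the operator order inside `T_Theta` is translate-then-rotate; the
  alternative order is available via an argument because for small motions
  the difference is below the interpolation error.

After corruption the spectrum loses conjugate symmetry, so the
reconstruction is complex; the package reports the discarded imaginary
residue and uses the magnitude image, which is what clinical viewers
display.

## Severity presets

Three presets parameterize corruption severity: `minor`, `moderate` and
`heavy` perturb 5, 10 and 15 PE slabs respectively, each 3–7 lines wide,
with rotations uniform in ±7° and translations uniform in ±5 mm per axis.
Slabs are rejection-sampled to be pairwise disjoint — overlapping slabs
would make the per-line provenance ambiguous and the splice sum ill-defined
— and to avoid a protected central band of 8% of PE lines (the center of
k-space carries almost all image energy; corrupting it would destroy the
image rather than produce the ghosting/ringing artifacts of interest). Both
the band width and every preset field are configurable. Each slab carries
its own independent motion parameters: distinct abrupt movements.

A consequence worth knowing: the heavy preset needs roughly
`15 slabs x up to 7 lines + center band` free PE lines, so it requires
grids of at least ~112 lines. Requests that cannot be placed fail with the
required height in the message rather than silently overlapping slabs.

## The phantom generator

Real training corpora (e.g. T1-weighted brain volumes) are multi-gigabyte
downloads; the package instead ships a generator whose samples have the two
properties that matter for this task:

* a bright elliptical rim (emulating subcutaneous fat, the dominant source
  of motion ghosting) enclosing
* a piecewise-smooth interior of 4–8 randomized overlapping tissue
  ellipses, all normalized to [0, 1] on a zero background.

The rim is constructed to be at least 1.5× brighter than the interior mean.
Randomized compositions keep the detection task non-degenerate across
samples. What the phantoms do *not* emulate: anatomical texture, noise,
bias fields, multi-coil effects, or T1/T2 contrast. Passing tests therefore
demonstrate that the simulation physics, the losses and the optimization
behave as designed — not that the trained weights transfer to clinical
data, which requires training at full scale on real volumes.

Default phantom size is 128 px (native), with 64 px used by the CPU-scale
training harness; both are far below clinical resolution, chosen so the
whole pipeline trains in minutes on one core.

## Motion detection

The detector is a U-net over a 2-channel k-space representation of the
corrupted slice, followed by the *spatial averaging module*: the raw 2D
sigmoid map is averaged along the frequency-encoding axis, producing one
value per PE line (a projection — averaging twice changes nothing). The
outermost 5% of lines at each k-space edge are excluded from prediction and
loss; these peripheral lines carry almost no signal and their predictions
are dominated by noise. The loss is the sum of a soft Dice term
(`eps = 1e-6`) and binary cross-entropy, computed on the averaged,
peripherally-restricted per-line masks. Binarization at 0.5 is used for
reporting and for the data-consistency mask only; losses act on the soft
mask.

The input representation was selected empirically at desk scale. The
obvious pairing of log-magnitude with normalized phase generalizes poorly:
the phase of neighbouring PE lines of natural images is essentially
decorrelated, so the phase channel behaves as sample-specific noise that a
small network memorizes (held-out Dice ≈ 0.59 versus ≈ 0.83 for the chosen
default). The default representation instead pairs the log-magnitude with
its discrete Laplacians along the PE axis at neighbour distances 1 and 2,
which directly expose lines whose magnitude profile is inconsistent with
their neighbours — the signature of a spliced line — at the two scales a
3–7 line slab presents. Alternatives evaluated and rejected: a conjugate-symmetry
residual channel (it flags both the corrupted line and its conjugate
mirror, halving precision); complex line differences (no signal, for the
phase-decorrelation reason above); running-median magnitude residuals
(slab interiors are self-consistent, so only boundaries respond). The
`logmag_phase` and `logmag` representations remain selectable.

## Motion correction

The corrector is a residual U-net whose bottleneck carries Swin transformer
blocks: window multi-head self-attention plus a two-layer MLP, each behind
layer normalization with residual connections; every second block uses a
cyclically shifted window partition (no attention masking at the wrapped
boundary — at these window counts the simplification is immaterial and it
keeps the backward pass simple). The network predicts a correction that is
added to its input and clamped to [0, 1]; the output head is
zero-initialized so the untrained model is exactly the identity, which
makes the optimization start from "do no harm".

The training loss is

```
L = lambda_r * L1 + lambda_l * L_perc + lambda_d * L_dc,
    lambda_r = 10, lambda_l = 0.5, lambda_d = 100
```

with all three terms mean-reduced so the weights transfer across image
sizes. `L_perc` is a squared distance between the stage activations of a
small fixed convolutional pyramid (LPIPS-family). No pretrained perceptual
backbone is bundled; the default extractor uses frozen He-initialized
weights from a fixed seed, which preserves the property that matters —
high-frequency structured error is penalized more than smooth error of
equal L2 norm (asserted in the tests) — while keeping the package
self-contained. A trained backbone can be substituted through the same
interface. `L_dc` compares the masked k-space of the output against the
masked k-space of the reference; its gradient is computed in closed form
through the orthonormal FFT. The mask is the detector's binarized
prediction, detached — no gradient flows from the corrector's loss into the
detector (a `dcMask = "ground_truth"` switch exists because the source
material is ambiguous about which mask enters this loss; the predicted
mask is the default as it is the only one available at inference).

## Joint training

"Trained simultaneously" is implemented as alternating per-batch steps:
detector update under Dice+BCE, then corrector update under the composite
loss using the just-computed (detached) masks. Adam with betas (0.9, 0.999)
throughout; no learning-rate schedule. Two presets exist:

* `paper`: batch 32, lr 2e-4, 25 epochs — the reference configuration for
  full-scale corpora;
* `desk`: batch 4, lr 2.5e-3, 200 joint steps — the CPU-scale
  configuration used by the test harness, sized so a full joint run on 8
  phantoms at 64 px completes in a few minutes on one core. The higher
  learning rate compensates for the ~100× smaller step budget; rates at
  5e-3 and above destabilize the corrector.

The desk harness trains on the `minor` severity: at 64 PE lines the
moderate and heavy presets corrupt most of the available lines, which
degenerates the detection task (predicting "everything is corrupted" is
then nearly optimal). Everything is seeded — parameter init, batch order,
bootstrap resampling — and with a single BLAS thread two runs with the same
seed produce bit-identical loss curves. A non-finite loss aborts training
and returns the last finite-state checkpoint.

Because no deep-learning framework is part of this package's dependency
footprint, the networks run on a small reverse-mode differentiation engine
implemented here (im2col convolutions over BLAS, window attention, layer
norm, the losses). Every differentiation rule is verified against central
finite differences in the test suite.

## Evaluation

Per-slice PSNR (dB, range 1, perfect matches capped at 100 dB so means stay
finite), SSIM (Gaussian 11×11 window, sigma 1.5, K1 = 0.01, K2 = 0.03,
population moments, valid-region mean — cross-checked against an
independent reference implementation to 1e-4) and NMSE. NMSE conventions
vary across the literature; here it is `||xhat - x||² / ||x||² x 100`
(percent), with the reference in the denominator. Group summaries use
bootstrap confidence intervals (10,000 resamples; bias-corrected and
accelerated by default, percentile available; a constant sample yields a
zero-width interval with a warning) and between-method comparisons use
one-way ANOVA followed by Tukey's HSD at alpha = 0.05. Metrics aggregate
per slice.

## Problem sizes used by the checks

The package's own verification runs at sizes chosen for a single CPU core:
Fourier/splice properties on 16–64 px grids; severity monotonicity over 20
phantoms at 128 px; the end-to-end training check on 8 training phantoms at
64 px for 200 joint steps (seed 7), asserting a ≥10× segmentation-loss
drop, held-out binarized-mask Dice ≥ 0.8 and a ≥3 dB PSNR gain over the
corrupted input. Dice is computed over the detector's prediction domain
(the non-peripheral PE lines): ground-truth lines inside the excluded
peripheral bands are forced misses by construction, so including them
would measure the exclusion design, not the detector. A loss-ablation
direction check (full composite loss vs L1-only, heavy severity at 128 px,
matched data and 3 matched seeds) asserts that the full loss does not
worsen held-out NMSE. These miniatures exercise every code path of the
full-scale configuration; they do not reproduce full-scale restoration
quality.

The ablation check deserves a candid note. The data-consistency term is a
reweighted subset of the same clean-target objective, and on the
*training* objective the composite loss reliably fits better; on
*held-out* phantoms its margin at miniature scale is thin and
schedule-dependent. At the check's short schedule the direction holds,
but with longer desk schedules on the same 8–14 phantoms the strongly
weighted consistency term's high-frequency fitting pressure turns into
small-data overfitting and the direction reverses. The clear benefit
reported for the composite loss belongs to the full-scale training regime
(tens of thousands of slices), which is out of reach on one core — a
miniature of this check measures the direction, not the effect size.

## Known limitations

* In-plane rigid motion only; no through-plane, intra-line, or non-rigid
  motion, no spin-history/B0 effects, single-coil Cartesian sampling.
* The phantom family is geometric; no claim of anatomical realism.
* The perceptual term uses a randomized extractor by default, not a
  pretrained network.
* Detection assumes line-structured corruption; per-coefficient corruption
  is out of scope.
* The desk-scale trained weights are demonstrations, not clinically usable
  models.
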