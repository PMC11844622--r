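# kmoco — physics-informed motion simulation, detection and correction for brain MRI k-space

Rigid head motion during a Cartesian MR acquisition displaces individual
phase-encoding (PE) lines of k-space: every line acquired after an abrupt
movement samples the Fourier transform of a rigidly transformed object.
The result in image space is ghosting and ringing, one of the most common
artifacts in high-resolution brain MRI. `kmoco` is an R implementation of a
physics-informed correction pipeline for this problem, aimed at researchers
studying motion-robust reconstruction who want a self-contained, fully
seeded, CPU-scale testbed:

* **Simulation.** Corruption is modelled exactly as the physics dictates:

  ```
  k_motion = (1 − M) ⊙ k_GT + M ⊙ T_Θ(k_GT),   T_Θ = F ∘ R_θ ∘ T_(tx,ty) ∘ F⁻¹
  ```

  with a binary PE-line mask `M` over disjoint slabs and an independent
  rigid transform `Θ = (θ, tx, ty)` per slab. Severity presets `minor` /
  `moderate` / `heavy` corrupt 5 / 10 / 15 slabs of 3–7 lines, |θ| ≤ 7°,
  |t| ≤ 5 mm; the center of k-space is protected. Unspliced lines stay
  **bit-identical** to the clean spectrum.

* **Detection.** A U-net over a two-channel k-space representation of the
  corrupted slice, followed by a spatial-averaging module (per-line mean
  along the frequency-encoding axis) and peripheral exclusion, trained with
  `L_seg = L_Dice + L_BCE`.

* **Correction.** A residual U-net with Swin-transformer blocks at the
  bottleneck, trained with

  ```
  L = λ_r‖x̂ − x‖₁ + λ_l L_perc(x̂, x) + λ_d‖F(x̂)⊙M_p − F(x)⊙M_p‖²₂,
  λ_r = 10, λ_l = 0.5, λ_d = 100
  ```

  where `M_p` is the detector's (detached) predicted mask — the data-
  consistency term anchors exactly the k-space lines the detector flags.

* **Evaluation.** PSNR / SSIM / NMSE per slice, bootstrap 95% CIs
  (percentile and BCa, 10,000 resamples), one-way ANOVA + Tukey HSD across
  methods.

Networks are trained by a small reverse-mode differentiation engine built
into the package (im2col convolutions over BLAS, window attention, layer
norm); every gradient rule is finite-difference checked in the tests. A
synthetic brain-like phantom generator (bright skull-like rim over
piecewise-smooth tissue ellipses) stands in for clinical corpora so the
entire pipeline runs in minutes on one core with no downloads.

## Worked example

```r
library(kmoco)

img <- generatePhantom(phantomSpec(size = 128, seed = 1))
sim <- simulateMotion(img, severityPreset("moderate"), seed = 2)

psnr(sim$corrupted, img)   # 22.10 dB
ssim(sim$corrupted, img)   # 0.5909
nmse(sim$corrupted, img)   # 5.236 %
sim$mask                   # LineMask over 128 PE lines (binary), 51 line(s) flagged
```

The corrupted phantom shows the classic artifact pattern: replicated
ghosts of the bright rim along the PE direction and ringing in the
interior, and quality degrades monotonically through the presets (medians
over 20 phantoms: ~29 dB minor, ~22 dB moderate, ~21 dB heavy).

Joint training at desk scale (8 training phantoms at 64 px, batch 4,
200 alternating detector/corrector steps — a few minutes on one core):

```r
arch <- generateDataset(16, phantomSpec(size = 64, seed = 1),
                        split = c(0.5, 0.5), severities = "minor", seed = 1)
fit  <- trainModels(arch, "minor", trainConfig("desk", seed = 7),
                    detectionConfig(), correctionConfig())

## segmentation loss collapses ...
head(fit$losses$lseg, 1); mean(tail(fit$losses$lseg, 10))

## ... detection generalizes to held-out phantoms ...
pred <- detectMask(toKSpace(corruptedSlices(arch, "minor")[[9]]), fit$detector)

## ... and correction beats the corrupted input on PSNR
xc <- corruptedSlices(arch, "minor")[[1]]
psnr(correctSlice(xc, fit$corrector), cleanSlices(arch)[[1]]) -
  psnr(xc, cleanSlices(arch)[[1]])
```

A command-line interface wrapping the same functions ships in
`inst/scripts/kmoco` (subcommands `simulate`, `make-fixtures`, `train`,
`correct`, `evaluate`; each writes a JSON run manifest with the seed and a
config hash).

## Scope

2D, single-coil, Cartesian, in-plane rigid motion. Through-plane and
non-rigid motion, spin-history/B0 effects and non-Cartesian trajectories
are out of scope. See the methods vignette
(`vignettes/kmoco-methods.Rmd`) for the model, the design decisions and
the known limitations.
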