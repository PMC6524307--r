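---
title: "Methods: MVCT enhancement by block matching and discriminative feature representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MVCT enhancement by block matching and discriminative feature representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvctenhance)
```

## Problem

Megavoltage CT (MVCT) images acquired on helical TomoTherapy units are
used for patient setup and adaptive dose recalculation. Compared with
planning kilovoltage CT (KVCT), MVCT slices show markedly higher noise
and compressed soft-tissue contrast, which makes low-contrast anatomy
hard to delineate. The enhancement method implemented here denoises
MVCT slices while transferring soft-tissue appearance learned from
registered KVCT data, under the hard constraint that calibrated
Hounsfield units (HU) stay usable for dose calculation.

## Method overview

The pipeline processes one slice at a time on a display-windowed scale
(width 400 HU, level 40 HU, mapped linearly to 0–255; pixels at or
beyond the window limits are passed through verbatim so air and bone
keep their calibrated HU).

1. **Block matching.** For every reference position on a sliding grid
   (interval 3 px, 8×8 patches), the most similar patches inside a
   39×39 search window are stacked into a 3D group of up to 5 blocks.
   Similarity is squared L2 distance per pixel pair on the windowed
   scale; patches farther than the match threshold 400 are excluded.
2. **Discriminative sparse coding (the DFR step, optional).** Each
   group, after per-block DC removal, is coded by orthogonal matching
   pursuit (OMP) over a two-part dictionary `D = [D_hq | D_na]`:
   `D_hq` holds 8×8×5 atoms extracted from KVCT-like training volumes
   (high-quality structure), `D_na` holds atoms extracted from the
   KVCT−MVCT difference (the noise/artifact model). The pursuit is
   capped at 10 atoms; reconstruction keeps only the `D_hq`
   contributions plus the per-block DC, discarding content the model
   attributes to noise.
3. **Collaborative filtering.** Each group is transformed with a
   separable 3D transform — a biorthogonal 1.5 wavelet (full
   multilevel decomposition) within each block and an orthonormal
   transform along the stack — hard-thresholded at `lambda_3d * sigma`
   (default 2.7), and transformed back.
4. **Aggregation.** Every filtered block is returned to its image
   position and overlapping estimates are averaged with weights
   `1 / (sigma^2 * N_retained)`, where `N_retained` is the number of
   coefficients surviving the threshold, so sparser (more confident)
   groups dominate.

The plain BM3D arm is steps 1, 3, 4; the full method inserts step 2.

## Parameters

| Key | Default | Unit | Role |
|---|---|---|---|
| `n_block` | 8 | px | patch side |
| `n_number` | 5 | blocks | maximum group depth |
| `window` | 39 | px | search window side |
| `step` | 3 | px | reference sliding interval |
| `tau_match` | 400 | (0–255)² per pixel | match threshold |
| `lambda_3d` | 2.7 | – | hard-threshold coefficient |
| `sigma` | `"auto"` | 0–255 scale | noise sd; estimated if `"auto"` |
| `c_dfr` | 10 | atoms | OMP sparsity cap |
| `atom_nx/ny/nz` | 8/8/5 | px | dictionary atom geometry |
| `k_hq`, `k_na` | 256 each | atoms | sub-dictionary sizes |
| `rho_max` | 0.9 | – | maximum inter-atom coherence |
| `window_width/level` | 400/40 | HU | processing/display window |

The patch geometry, group depth, search window, sliding interval,
match threshold, sparsity cap, atom size and display window are the
standard parameter set of the method; `lambda_3d = 2.7` is the
classic BM3D hard-threshold coefficient. All of them are exposed
through `run_config()` and the flat `key = value` config file read by
the command-line tool.

## Numerical choices

- **Wavelet.** The per-block 2D transform is the biorthogonal 1.5
  wavelet with half-sample symmetric extension, applied as a
  precomputed matrix; the synthesis matrix is the exact inverse of the
  analysis matrix, so round trips are accurate to ~1e-15.
- **Stack transform.** An orthonormal Hadamard transform when the
  group depth is a power of two, an orthonormal DCT-II otherwise
  (the default depth is 5), identity for singleton groups. Both are
  isometries, so thresholds act on comparable coefficient scales.
- **Noise estimation.** `sigma = "auto"` uses the median absolute 2×2
  Haar HH coefficient divided by 0.6745 on the windowed image,
  excluding cells touching clipped pixels (exactly 0 or 255). Without
  that exclusion, images dominated by out-of-window air would estimate
  zero noise and the filter would degenerate to a no-op.
- **Determinism.** Block-matching ties resolve in row-major scan
  order, OMP ties take the lowest atom index, and all simulation
  noise is drawn under locally seeded RNG that restores the caller's
  state. Repeated runs are bit-identical.
- **Performance.** Block matching and batch OMP are C++
  (RcppArmadillo); transforms are batched matrix products in R. A
  256×256 slice takes on the order of 10 s on one CPU.

## Synthetic phantom

Because no clinical scans can ship with the package, evaluation uses a
Catphan-like digital phantom: a 256×256 slice with a 100 px water body
(0 HU) in air (−1000 HU) and four plugs (−100, −40, +40, +120 HU,
radius 12). The MVCT degradation model applies, in order, soft-tissue
contrast compression toward the soft-tissue mean (factor 0.85 within
±400 HU), Gaussian detector blur (sd 0.5 px), and additive Gaussian
noise (sd 20 HU); the KVCT model uses sd 3 HU, no blur, full contrast.
These defaults emulate the qualitative MVCT/KVCT difference (noise
several times higher, soft-tissue contrast visibly compressed) and
were fixed before the pipeline was evaluated on them.

Realism limits worth keeping in mind: the noise is white Gaussian in
image space rather than correlated reconstruction noise; there are no
beam-hardening, ring, or motion artifacts; contrast compression is a
global linear map instead of an energy-dependent attenuation model;
and training pairs are perfectly registered by construction, which
real deformably-registered KVCT/MVCT pairs are not.

## Evaluation

- **CNR** between a target plug and a body background ROI:
  `2 |A_t - A_b| / sqrt(a_t^2 + a_b^2)` with population standard
  deviations, plus a paired t comparison across slice cohorts.
- **Edge maps** via a deterministic Canny detector (Gaussian blur,
  Sobel gradients, non-maximum suppression, hysteresis), used to count
  spurious noise edges.
- **HU stability**: per-ROI mean drift, body RMS and maximum absolute
  HU change between input and output, with a 5 HU drift tolerance —
  the dose-calculation safety check.

Problem sizes used throughout development and testing: 256×256 slices
(~7.5k reference groups per slice), 512-atom dictionaries trained from
five 256×256 slice pairs, and 5-seed cohorts for the statistical
checks.

## Limitations

- Single-slice (2D) processing; the "3D" in BM3D refers to stacked
  similar patches, not volumetric filtering across slices.
- The dictionary is phantom-trained in the examples; clinical use
  would require registered KVCT/MVCT training data of the same anatomy
  class.
- Hard thresholding only (no second Wiener stage).
- The DICOM reader/writer covers only single-frame uncompressed
  explicit-VR little-endian CT images.
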