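# mvctenhance

Enhancement of megavoltage CT (MVCT) slices from helical TomoTherapy
units. MVCT images are used for daily patient setup and adaptive dose
recalculation, but compared with planning kilovoltage CT (KVCT) they
are noisy and show compressed soft-tissue contrast. This package
implements a patch-based enhancement method that combines:

- **Block matching**: similar 8×8 patches (`N_number` ≤ 5, search
  window `L` = 39, sliding interval `Δd` = 3, match threshold
  `τ_match` = 400) are stacked into 3D groups;
- **Discriminative feature representation (DFR)**: each group is
  sparse-coded by orthogonal matching pursuit (cap `C_DFR` = 10) over a
  two-part dictionary `D = [D_hq | D_na]` of 8×8×5 atoms — `D_hq`
  learned from KVCT-like data, `D_na` from the KVCT−MVCT difference —
  and rebuilt from the high-quality atoms only;
- **Collaborative filtering**: a separable 3D transform (biorthogonal
  1.5 wavelet per block, orthonormal transform along the stack) with
  hard thresholding at `λ_3D σ` (`λ_3D` = 2.7);
- **Weighted aggregation**: overlapping block estimates averaged with
  weights `1/(σ² N_retained)`.

Processing happens on a 400/40 HU display window; pixels outside the
window (air, bone) pass through bit-exactly, so calibrated HU stay
usable for dose calculation. A plain BM3D arm (no DFR step) is included
for comparison, along with CNR / Canny-edge / HU-stability evaluation,
a Catphan-like digital phantom with an MVCT/KVCT degradation model,
readers and writers for NIfTI, a minimal uncompressed DICOM subset and
a raw-binary fixture format, and a command-line interface.

## Worked example

```r
library(mvctenhance)

# build a training dictionary from registered phantom KVCT/MVCT pairs
pairs <- make_training_pairs(seed = 42)
dict  <- build_dictionary(pairs)
print(dict)
#> <feature_dictionary> 256 HQ + 256 NA atoms of 8x8x5

# simulate an MVCT slice of the default phantom and enhance it
scene <- make_eval_scene(seed = 7)
bm3d <- enhance_slice(scene$mvct, pipeline_config(method = "BM3D"))
dfr  <- enhance_slice(scene$mvct,
                      pipeline_config(method = "BM3D_DFR", dict = dict))

for (x in list(original = scene$mvct, bm3d = bm3d, dfr = dfr))
  print(cnr(x, scene$target, scene$background))
#> CNR 2.5452  (target -34.4 +/- 17.6, background -0.8 +/- 19.7)
#> CNR 26.1123  (target -33.4 +/- 1.8, background -0.0 +/- 1.9)
#> CNR 37.7218  (target -33.1 +/- 1.7, background -0.0 +/- 0.5)

hu_stability(scene$mvct, dfr,
             rois = list(scene$target, scene$background),
             body_mask = scene$body_mask)
#> HU stability: RMS 19.76, max |diff| 79.54, ROI drift 1.31/0.76 HU -> stable
```

The low-contrast plug's CNR rises from 2.55 (input) to 26.11 (BM3D)
and 37.72 (BM3D+DFR), while the ROI mean HU move by at most 1.31 HU —
well inside the 5 HU tolerance used for dose-calculation safety. (The
body RMS of ~20 HU is the removed noise itself; the drift of the ROI
means is the quantity that matters for calibration.)

The same workflow is available from the shell via the CLI wrapper in
`inst/cli/`:

```sh
mvctenhance simulate   --out work/phantom --seed 1
mvctenhance train-dict --pairs work/phantom --out work/dict
mvctenhance enhance    --input work/phantom_mvct --output work/enhanced \
                       --method bm3d+dfr --dict work/dict
mvctenhance evaluate   --original work/phantom_mvct --enhanced work/enhanced \
                       --rois work/phantom_rois.json --out work/eval.json
```

All tunables live in a flat `key = value` config file accepted by every
subcommand (`--config`); see `?run_config` for the full list and
defaults, and the vignette in `vignettes/` for the method description.

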