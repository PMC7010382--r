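# wrdmd — windowed and reconstruction DMD for DCE-MRI motion correction

Dynamic contrast-enhanced (DCE) MRI of the kidneys acquires a time series of
images while a contrast agent perfuses the tissue. The clinical readout — the
time–intensity curve of a kidney region of interest (ROI) — assumes the organ
stays put, but free-breathing acquisitions superimpose a pseudo-periodic
respiratory translation of a few pixels on the slow enhancement signal. That
motion corrupts the ROI curve and downstream perfusion estimates.

`wrdmd` removes this motion without registration, exploiting the different
time scales of enhancement and breathing:

1. **W-DMD (windowed dynamic mode decomposition).** A short window (default
   `W = 3` frames) slides over the sequence with stride 1. Within each window
   a DMD separates the least dynamic mode — the background/contrast content,
   image `C1` — from the remaining fast modes (`C2`), which carry the
   breathing displacement. Discarding `C2` suppresses most of the motion.
2. **R-DMD (reconstruction DMD).** A full-sequence DMD of the `C1` component
   orders the modes by eigenvalue phase angle (slowly varying modes first) and
   re-synthesises the sequence from the `k` most significant modes (default
   `k = 3`), removing residual flicker while preserving the enhancement
   dynamics.

Quality is quantified with two registration-free metrics: the **mean motion
magnitude** from exhaustive block matching (mean Euclidean norm of block
displacements between consecutive frames; smaller = more stable) and the
**degree of smoothness** `D = sd(diff(curve)) / |mean(diff(curve))|` of the
ROI time–intensity curve (scale- and shift-invariant; a linear ramp scores 0).

The package also ships a seeded synthetic renography phantom with ground
truth, NIfTI/TIFF/PNG i/o, and a command-line interface.

## Worked example

The default phantom is a 64 × 64 px, 120-frame sequence at 1.5 s per frame: an
enhancing kidney ellipse and liver band on a textured background, a vertical
2-px translation repeating every 3 frames (shallow breathing), and Gaussian
noise at 1 % of peak intensity.

```r
library(wrdmd)

phantom <- default_renography_phantom(seed = 1)
phantom
#> <phantom_output> 120 frames of 64 x 64 px, 2 region(s), seed 1

cfg <- block_match_config()    # 15x15 blocks, overlap 5, max displacement 5

# breathing period, from block matching each frame against the first
vs_first <- mean_motion_magnitude(phantom$stack, cfg, scheme = "vs_first")
estimate_period(vs_first$per_pair)
#> [1] 3

# raw motion level
mean_motion_magnitude(phantom$stack, cfg)
#> <motion_profile> consecutive scheme, 119 pairs, global mean 1.3653 px

# W-DMD -> full-sequence DMD of C1 -> reconstruction from the top 3 modes
wd  <- run_wdmd(phantom$stack, W = 3)
wd$c1$N
#> [1] 118                      # 120 - 3 + 1 windows
dec <- compute_dmd(wd$c1)
dec$d
#> [1] 117                      # full rank on 118 frames
corrected <- reconstruct(dec, order_modes(dec), k = 3)

mean_motion_magnitude(corrected, cfg)
#> <motion_profile> consecutive scheme, 116 pairs, global mean 0.0000 px

# ROI curve smoothness, before and after
degree_of_smoothness(time_intensity_curve(phantom$stack, phantom$masks$kidney))
#> [1] 29.39786
degree_of_smoothness(time_intensity_curve(corrected, phantom$masks$kidney))
#> [1] 5.323778
```

The residual motion drops from 1.37 px to 0.00 px (100 % reduction) and the
kidney curve's degree of smoothness improves from 29.4 to 5.3. The one-call
equivalent of the correction steps is `run_wrdmd(phantom$stack, W = 3, k = 3)`.

Retaining more modes re-admits the motion that the significance ordering
pushed to the back: the global mean motion of the reconstruction grows
monotonically over `k = 4, 8, 16, 32` (0.0000, 0.0081, 0.0219, 0.1190 px on
the phantom above).

## Command-line interface

An executable wrapper is installed at
`system.file("cli", "wrdmd", package = "wrdmd")`:

```sh
wrdmd simulate  --seed 1 --out-dir phantom
wrdmd correct   --input phantom/sequence.nii --output corrected.nii
wrdmd decompose --input phantom/sequence.nii --out-dir dmd
wrdmd evaluate  --input phantom/sequence.nii --corrected corrected.nii \
                --mask phantom/mask_kidney.png --out-dir evaluation
```

## Vignette

`vignettes/wrdmd-methods.Rmd` documents the model, the numerical design
decisions (mode ordering and pruning, amplitude fitting, the temporal
projection used for reconstruction) and the phantom's realism limits.
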