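# isimap

Retinotopic mapping of mouse visual cortex from intrinsic signal imaging
(ISI) through the intact skull: phase-encoded ("periodic stimulation")
analysis, visual field sign (VFS) maps, automated segmentation of visual
areas, trial-count reliability analysis, vasculature-based alignment for
craniotomy targeting, and validation of the imaging-derived maps against
laminar local field potential (LFP) recordings.

Everything is testable without experimental data: the package ships a
synthetic-data generator that produces reflectance movies, vasculature
images and laminar LFP responses with known ground truth.

## The method in brief

A drifting bar sweeps periodically across the visual field (drift
frequency 0.055 Hz, 18 s per sweep, 10 sweeps per 180 s block) while the
cortex is imaged under red light. Each cortical point responds once per
sweep, when the bar crosses its receptive field, so the *temporal phase*
of the response at the drift frequency encodes the *visual-field
position* of that point:

1. **Absorbance.** Reflectance frames are converted to absorbance by the
   modified Beer–Lambert law, `ΔA = log10(I/I0)`, with `I0` the mean of
   the first seconds of baseline. Activation appears as an absorbance
   *increase* (a reflectance dip).
2. **Fourier projection.** Each pixel's trace is projected onto the
   stimulus frequency — a single exact-frequency DFT coefficient. The
   argument is the response phase; the modulus is the response strength.
3. **Trial QC.** Trials whose amplitude map lacks spatial structure
   (normalized spatial variance below a threshold) are discarded.
4. **Delay cancellation.** The phase contains an unknown hemodynamic
   delay. Opposing sweep directions carry the delay with the same sign
   but the retinotopic phase with opposite signs, so combining a
   forward/backward pair cancels the delay and yields absolute
   retinotopic phase, converted to visual degrees.
5. **Visual field sign.** The sign of `sin(angle(∇azimuth) −
   angle(∇elevation))` distinguishes mirror from non-mirror
   representations of the visual field; adjacent areas alternate sign,
   so thresholding and connected-component labelling segments the
   cortical areas automatically.
6. **Reliability.** Subsampling trials quantifies how map quality grows
   with trial count: centroid stability in µm, and ROC/AUROC
   detectability of each area's VFS patch against a non-visual noise
   region.
7. **Alignment and validation.** Maps are aligned to vasculature images
   by translation (phase correlation or landmark pairs) to target
   craniotomies; the ISI retinotopy predicted at a craniotomy is
   compared against preferred positions from laminar LFP recordings,
   with layers assigned around the earliest current-sink latency (layer
   4).

## Quick start

Simulate a six-area session in the study regime (96 px field, 2.5 Hz,
10 blocks per direction, 10 % planted bad trials) and recover the maps:

```r
library(isimap)

cfg    <- stim_config(smooth_sigma = 1.5)   # VFS gradient smoothing for 96 px
gt     <- make_ground_truth("six_area", image_size = 96, cfg = cfg,
                            hemodynamic_delay = 3)
params <- sim_params(image_size = 96, frame_rate = 2.5, n_blocks = 10, seed = 7)
session <- simulate_session(gt, params, cfg, seed = 7)

paired <- qc_and_pair(session, threshold = cfg$qc_threshold)
length(paired$pairs_az)
#> [1] 88        # 100 sweep-trials per direction, bad ones discarded, then paired

az  <- build_axis_map(paired$pairs_az, cfg)   # azimuth in visual degrees
el  <- build_axis_map(paired$pairs_el, cfg)
vfs <- visual_field_sign(az, el, sigma = cfg$smooth_sigma)

median(abs(az$values - gt$azimuth_true)[gt$mask], na.rm = TRUE)
#> [1] 0.532     # deg, across all six areas

areas <- segment_areas(vfs, threshold = 0.3, min_size = 100)
rois  <- setNames(lapply(gt$areas, `[[`, "mask"),
                  vapply(gt$areas, `[[`, "", "name"))
match_segments(areas, rois)
#>   reference segment   overlap sign
#> 1        V1      A1 0.9381847    1
#> 2        LM      A2 0.9691120   -1
#> 3        AL      A3 0.9377990    1
#> 4        RL      A5 0.9297297   -1
#> 5        AM      A7 0.7407407    1
#> 6        PM      A4 0.9227053   -1
```

All six generator areas are recovered with the correct visual field sign
(V1 mirror `+1`, LM non-mirror `-1`, …). `plot(az)` and `plot(vfs)` draw
the maps; `save_overlay_png()` renders areas and planned craniotomies
over the vasculature image.

### Reliability

```r
np   <- length(paired$pairs_az)
subs <- setNames(lapply(c(5, 20, 60, np), function(n)
  subsample_average(paired$pairs_az, n, n_reps = 6, seed = n,
                    cfg = cfg, pairs_el = paired$pairs_el)),
  c(5, 20, 60, np))
curve  <- centroid_error_curve(subs, az, mask = rois$V1)
n_star <- min_trials_for_criterion(curve, criterion = 100)  # µm
roc    <- roc_detectability(subs, vfs, rois, noise_roi_outside(rois, 10))
```

### Command line

A thin front end lives in `inst/cli/isi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/isi.R", package="isimap"))')" \
  fieldsign --out run1 --seed 4 --preset six_area
```

Subcommands `simulate`, `process`, `fieldsign`, `reliability` and `run`
execute the pipeline up to the named stage, logging one JSON line per
stage and writing TIFF maps (each with a JSON sidecar carrying the
encoding and axis metadata), `areas.json`, `error_curve.csv` and a
`manifest.json` that records every parameter, seed and output. Re-running
with the same seed reproduces the outputs byte for byte.

## Testing

```r
testthat::test_dir("tests/testthat", package = "isimap",
                   load_package = "installed")
```

The suite (about 2 minutes) checks every stage against closed-form
oracles — brute-force DFT sums, threshold-sweep ROC integration,
covariance-formula correlations, planted registration shifts, an
exhaustive layer-partition oracle — plus end-to-end recovery of known
ground truth. `tests/testthat/test-acceptance.R` holds the headline
claims, one `test_that()` block each.

## Package layout

| Path | Contents |
| --- | --- |
| `R/config.R`, `R/stack.R`, `R/trials.R` | stimulus config, TIFF/CSV/JSON IO, trial segmentation |
| `R/simulate.R` | ground-truth layouts, reflectance movies, vasculature, LFP |
| `R/preprocess.R` | Beer–Lambert absorbance, translation registration |
| `R/phasemap.R` | Fourier projection, QC, averaging, delay cancellation, degree maps |
| `R/fieldsign.R` | smoothing, VFS, segmentation, contours |
| `R/reliability.R` | subsampling, centroid error curves, AUROC detectability |
| `R/alignment.R` | vasculature/landmark alignment, craniotomy targeting |
| `R/ephys.R` | laminar LFP, layer assignment, ISI-vs-LFP statistics, tuning |
| `R/pipeline.R` | `run_pipeline()`, manifests, map files, overlays |
| `vignettes/` | methods notes: conventions, design choices, calibration |
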