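# nirpol

Detection and segmentation of **ambient-light pollution** in
spatio-temporal near-infrared fluorescence optical imaging (NIR-FOI)
stacks.

NIR-FOI records the distribution of an injected fluorescent colour agent
(indocyanine green) in a patient's hands as an `x × y × t` stack. Ambient
light — from windows, doors or room lights — contaminates the measured
counts and confounds any analysis of the dye kinetics. `nirpol` computes a
single 2-D pollution map per dataset, marking every pixel that is polluted
at any point of the acquisition, using three stages:

1. **Per-phase core detection.** The acquisition splits into a
   no-colour-agent (NoCA) phase, an illumination phase and a flush-out
   phase. In the NoCA phase each pixel's timeline is Fourier transformed,
   every retained component is z-scored across pixels,
   `PXL_i = Σ_j (pxl_ij − μ_j)/σ_j`, and the summed score image is
   thresholded robustly. In the flush-out phase each frame is Gaussian
   high-pass filtered in the 2-D frequency domain, per-pixel temporal
   standard deviations are computed interval-wise, min-max normalized,
   summed, rescaled to 0–255 and thresholded. NoCA-flagged pixels are
   excluded from all later statistics.
2. **Seeds and training data.** Each 8-connected core area gets a seed
   (floored centroid, snapped into the region) and a balanced two-class
   training set: Class1 = the area's whole-phase pixel timelines, Class0 =
   an equal number of timelines sampled outside a dilated forbidden zone
   around all detected areas, with a minimum spacing between picks.
3. **kNN-gated region growing.** From each seed, breadth-first growth
   classifies every frontier neighbour's *entire timeline* with that
   region's k-nearest-neighbour classifier (k = 3, Euclidean distance);
   Class1 training pixels are accepted without classification. The final
   map is the union of all grown regions with the NoCA core, and F1 = 2TP/(2TP+FP+FN)
   based metrics (pixel Dice χ, area-detection F1 ψ, dataset-verdict F1 τ)
   score the result.

Because clinical NIR-FOI data is not publicly available, the package
includes a synthetic generator (`simulate_stack()`, `default_suite()`)
producing three-phase stacks with a hand-like object, configurable
pollution phenotypes (static / fluctuating / onset-fluctuating) and exact
ground truth.

## Worked example

```r
library(nirpol)

# a 64 x 64 x 120 stack with one fluctuating pollution ellipse
cfg <- sim_config(rng_seed = 7, phenotypes = list(
  pollution_spec("fluctuating", "ellipse", y = 10, x = 54,
                 ry = 3.2, rx = 3.2, amplitude = 80, period = 12)))
sim <- simulate_stack(cfg)

res <- run_pipeline(sim$stack, pipeline_config(rng_seed = 1))
res$map
#> <pollution_map> 64 x 64, 38 polluted pixel(s), 1 region(s)
res$report$phases
#> $ssp
#> [1] 19
#>
#> $tpfi
#> [1] 51

ev <- evaluate_against_truth(res$map, sim$truth)
unlist(ev[c("dice", "area_f1", "predicted_polluted")])
#>               dice            area_f1 predicted_polluted
#>          0.9866667          1.0000000          1.0000000
```

The detected phase boundaries (frames 19 and 51) match the simulated onset
at 20 and peak at 50 within the smoothing shift; the grown region recovers
the planted ellipse almost exactly (Dice 0.987), and the dataset is
correctly flagged polluted.

A thin command-line wrapper over the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "nirpol", package = "nirpol"))') \
    segment stack.tif --out results/ --seed 1
```

with subcommands `segment`, `simulate`, `evaluate` and `report`.

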