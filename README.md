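# inclusionKit

Quantitative imaging and flow-cytometry analysis of Huntingtin exon-1
(Httex1) inclusion bodies in cultured cells.

Cells expressing Httex1 with an expanded polyglutamine tract form dense
intracellular inclusions. Whether an inclusion is newly formed or mature,
what it recruits, how porous and how mobile its contents are, and how its
formation depends on expression level are all measurable with fluorescence
microscopy and cytometry — but each readout needs careful, reproducible
pixel- and event-level arithmetic. `inclusionKit` packages that arithmetic
for R users, together with a seeded synthetic-data generator so every
analysis stage can be validated against known ground truth.

## What it computes

* **Ratiometric maturity classification.** A tetracysteine-tagged Httex1
  binds the FlAsH dye only in its disordered (pre-amyloid) conformation.
  With per-experiment population mean μ and standard error s of the
  FlAsH:Cerulean intensity ratio, an inclusion with ratio x is classified

  * HBR (Highly Biarsenical-Reactive, recently formed) if x > μ + s,
  * PBR (Poorly Biarsenical-Reactive, mature) if x < μ − s,
  * INTERMEDIATE otherwise (reported, never silently dropped).

* **Radial zone enrichment** of co-recruited proteins (HaloTag/TMR) and
  RNA (EU/AF647): core / middle zones by normalized centroid-to-boundary
  distance, plus the outer ring between the segmented inclusion edge and
  the edge scaled by 110%; OLS regression of compartment intensity on
  maturity ratio with a 95% confidence band.

* **FRAP relative recovery.** With bleached (B), unbleached (U) and
  background (G) ROI means per frame,
  `r(t) = (B(t) − G(t)) / (U(t) − G(t))`,
  summarized by Δr = r(t_end) − r(t0) and a single-exponential fit
  `r(t) − r(t0) = A (1 − 2^(−t/τ))`, where A / (1 − r(t0)) estimates the
  mobile fraction and τ the recovery halftime.

* **Antibody penetration** into inclusions: mean centroid-to-boundary
  distance of the 110%-scaled external boundary minus that of the
  unstained-core (internal) boundary, in pixels.

* **Pulse-shape cytometry gating** (inclusion-bearing cells have
  narrower/taller pulses at a given pulse area), 20 log-spaced expression
  bins × 4 modifier categories, and the inclusion fraction per bin — the
  dose–response surface of aggregation.

* **Ribosome-stall reporter ratios**: per-construct median mCherry:GFP
  for GFP–test–mCherry cassettes, where stalling lowers the ratio toward
  1 − stall efficiency.

All image operations work on an exact pixel-set ROI representation with
deterministic thresholding (Otsu), 8-connected components, 4-neighbor
boundaries, geometric scaling and set algebra.

## Worked example

Classify a synthetic mature inclusion and verify the immobile FRAP
phenotype:

```r
library(inclusionKit)

# a scene whose true FlAsH:Cerulean ratio is 0.049 (a mature inclusion)
sc  <- render_scene(scene_spec(flash_cerulean_ratio_target = 0.049,
                               background_level = 2, noise_sigma = 4, seed = 2))
roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
ratio <- flash_cerulean_ratio(
  mean_intensity(get_channel(sc$image, "flash"), roi),
  mean_intensity(get_channel(sc$image, "cerulean"), roi))
classify_maturity(ratio, maturity_thresholds(mean = 0.063, sem = 0.002))
#   ratio: 0.051 -> label: PBR

# an immobile inclusion shows no FRAP recovery
fs  <- simulate_frap(frap_spec(mobile_fraction = 0, noise_sigma = 5, seed = 3))
res <- analyze_frap(fs)
res$summary$delta_recovery
# -0.0062   (flat curve: r(t) stays at ~0.50 for all 21 post-bleach minutes)
```

The ratio printed above (0.051) sits below the lower threshold
0.063 − 0.002 = 0.061, hence PBR: a mature, poorly FlAsH-reactive
inclusion. The FRAP delta of −0.006 is indistinguishable from zero,
the no-recovery phenotype of a rigid aggregate.

A command-line front end over the same functions lives at
`inst/cli/inclusionkit.R`, with subcommands `simulate`, `segment`,
`maturity`, `zones`, `frap`, `penetration`, `cytometry` and `stall`,
a YAML/JSON config, and a JSON run report per stage.

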