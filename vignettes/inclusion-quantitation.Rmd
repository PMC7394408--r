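---
title: "Quantifying Httex1 inclusion biology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Httex1 inclusion biology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inclusionKit)
```

# The biological measurements

Cells expressing aggregation-prone Huntingtin exon 1 (Httex1) with an
expanded polyglutamine tract form dense cytoplasmic inclusion bodies.
`inclusionKit` implements the quantitative readouts used to characterize
these inclusions from multi-channel fluorescence images and flow-cytometry
event tables:

1. **Maturity classification.** A tetracysteine (TC) tag near the polyQ
   tract binds the biarsenical dye FlAsH only while Httex1 is in a
   disordered conformation; amyloid-converted (mature) inclusions lose
   FlAsH reactivity. The per-inclusion FlAsH:Cerulean mean-intensity
   ratio therefore separates recently formed, Highly Biarsenical-Reactive
   (HBR) inclusions from mature, Poorly Biarsenical-Reactive (PBR) ones.
   Because absolute ratios are instrument- and experiment-specific, the
   classifier is calibrated per experiment: with population mean $\mu$ and
   standard error of the mean $s$, an inclusion with ratio $x$ is labeled
   HBR when $x > \mu + s$, PBR when $x < \mu - s$, and INTERMEDIATE
   otherwise. Ties with the band edges are INTERMEDIATE (the inequalities
   are strict), and INTERMEDIATE inclusions are reported rather than
   silently dropped, so every population count is auditable.

2. **Zone enrichment.** Co-recruited proteins (HaloTag/TMR) and RNA
   (EU/AF647) distribute non-uniformly across inclusions. The inclusion
   ROI is partitioned by normalized radial distance into a `core` and a
   `middle` zone, plus an `outer_ring`: the band between the segmented
   inclusion edge and that edge scaled by 110%, which is where
   surface-coating proteins concentrate. Mean intensities per zone feed
   matched comparisons; ordinary least squares relates compartment
   intensities to maturity ratios, with a 95% confidence band for the
   mean response.

3. **FRAP mobility.** Half of an inclusion is photobleached and the
   recovery imaged at one frame per minute. Relative recovery is
   $r(t) = \frac{B(t) - G(t)}{U(t) - G(t)}$ where $B$, $U$, $G$ are the
   mean intensities of the bleached, unbleached and background ROIs in
   the same frame. Because numerator and denominator are
   background-corrected within each frame, $r(t)$ is invariant under
   affine gain/offset changes of the detector, and no pre-bleach
   renormalization is applied (the pre-bleach value is retained for
   reporting). Mobility is summarized by
   $\Delta r = r(t_{end}) - r(t_0)$ and by a single-exponential fit
   $r(t) - r(t_0) = A\,(1 - 2^{-t/\tau})$, whose amplitude over the
   bleach-induced drop, $A / (1 - r(t_0))$, estimates the mobile
   fraction.

4. **Antibody penetration.** Anti-GFP immunostaining of
   Cerulean-fusion inclusions probes their porosity. The inclusion is
   segmented from the cerulean channel and scaled by 110% to give the
   external boundary; the internal boundary is the edge of the unstained
   core, found by automatic thresholding of the inverted antibody signal
   within the inclusion. Penetration is the difference of the mean
   Euclidean distances from the outer-ROI centroid to external and
   internal boundary pixels. Note the geometric floor: with 110% scaling,
   a zero-depth surface stain still measures about 10% of the radius, so
   both raw distances are always reported.

5. **Pulse-shape cytometry.** Cells whose fluorescence is concentrated
   into an inclusion produce narrower, taller cytometer pulses at a given
   pulse area. The gate is a linear discriminant on
   $(\log \text{width},\ \log \text{height} - \log \text{area})$,
   calibrated on explicit positive/negative control populations. Gated
   events are assigned to 20 log-spaced cerulean (expression) bins
   spanning the recorded range and, per construct, to four ordered TMR
   categories (`none` below a detection floor; `low`/`medium`/`high` as
   three log-uniform bins from the floor to that construct's maximum).
   The fraction of inclusion-positive cells per (expression, modifier)
   cell is the dose–response surface of aggregation.

6. **Stall-reporter ratios.** In a GFP–test-sequence–mCherry cassette
   flanked by P2A/T2A ribosomal skip sequences, ribosome stalling within
   the test sequence lowers mCherry output relative to GFP; the
   per-construct median mCherry:GFP area ratio approximates
   $1 - \text{stall efficiency}$.

# The synthetic-scene generator

No raw microscopy or cytometry data accompany these analyses, so the
package ships a first-class, seeded generator whose outputs carry ground
truth that analysis code never reads.

**Images.** One circular cell contains one circular inclusion; each
channel has a radial intensity profile on normalized distance $d/r$ from
the inclusion center: `uniform` (optionally with a distinct cytoplasm
level), `shell` (enriched band from a fractional inner edge out to 110%
of the radius — surface-coating proteins sit at and just beyond the
segmented edge, which is exactly what the outer-ring measurement
captures), `coat` (stain confined to the outermost `coat_depth_px`
pixels, for penetration studies), and `excluded` (signal only in the
cytoplasm). Pixels read background + profile + Gaussian noise, clipped
at zero. The noise is additive Gaussian only; shot noise, PSF blur,
bleed-through and 3D structure are deliberately absent, so passing tests
demonstrate correctness of the measurement logic, not robustness to
every optical artifact of real data.

**FRAP series.** A pre-bleach frame is followed by 21 one-minute
post-bleach frames (the pre-bleach frame sits one frame interval before
$t_0$). The bleach removes `bleach_depth` of the fusion signal in the
half-disk right of the vertical diameter through the inclusion center —
an exact half-disk, matching the half-inclusion bleach geometry — and
the FlAsH dye in that half is destroyed without recovery, which is what
makes the FlAsH channel the marker of the unbleached region. The mobile
pool recovers as $m\,(1 - 2^{-t/\tau})$, a single-exponential in base-2
halftime parameterization chosen as the simplest model with a named,
directly recoverable parameter (at $t = \tau$, exactly half the mobile
pool has returned).

**Cytometry events.** Cerulean pulse area is log-normal (defaults:
`meanlog = log(1000)`, `sdlog = 1.2`, spanning roughly three decades as
in transient transfection); the modifier (TMR) is log-normal or absent
(`modifier_logmean = NULL` gives the mock population used for the TMR
detection floor). Inclusion probability is logistic in the natural-log
intensities with defaults `intercept = -8`, `beta_expression = 1`
(aggregation probability rising with expression), `beta_modifier = 0`.
Pulse width is log-normal around 50 a.u.; height is tied to area/width
(pulse area is conserved) with small multiplicative noise.
Inclusion-bearing events have width multiplied by
`1 - pulse_width_shift` and height by an additional
`1 + pulse_height_shift` (defaults 0.3 each). Stall populations emit
log-normal GFP and mCherry with
$E[\text{mCherry}]/E[\text{GFP}] = 1 - \text{stall efficiency}$.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| threshold method | Otsu | — | the de-facto automatic threshold in the imaging tools this workflow targets; recorded in ROI metadata because low-contrast regimes are method-sensitive |
| boundary scale factor | 1.10 | — | external boundary = segmented inclusion scaled by 110% |
| background circle radius | 25 | px | fixed-radius manual background ROI for FRAP normalization |
| zone fractions | (0.5, 1.0) | of normalized radius | the inner split between core and middle is not prescribed by the measurement; 0.5 is symmetric and configurable |
| expression bins | 20 | log-uniform | spanning the recorded positive range |
| TMR categories | 4 | log-spaced | `none` below floor + 3 bins to the per-construct maximum |
| TMR detection floor | 1st percentile of a mock population | a.u. | `none` is otherwise undefined on a log scale |
| FRAP frames | 21 post-bleach, 1/min | min | recovery window |
| bleach depth (generator) | 0.5 | fraction | deep enough to quantify recovery while keeping the bleached half within the inclusion's intensity class for automatic thresholding |

# Numerical choices and degenerate inputs

* **Coordinates** are 1-based `(row, col)` pixel centers, origin
  top-left — R's native matrix convention, which makes ROI set algebra
  exact integer arithmetic.
* **Connectivity** is 8-connected for components and 4-neighbor for
  boundaries, the standard pairing that keeps boundaries closed.
  Component ties are broken toward the component containing the
  lexicographically smallest pixel, so segmentation is deterministic.
* **ROI scaling** re-rasterizes the filled scaled shape by inverse
  mapping (a pixel belongs to the scaled ROI when its pre-image rounds
  into the original), rather than morphological dilation: scaling by
  110% is a geometric statement about the boundary, and inverse mapping
  honors it for any factor, including shrinkage.
* **Normalized radial distance** is computed per pixel as distance to
  the centroid divided by the distance of the boundary pixel nearest in
  angle within a ±10° window (nearest-angle fallback outside it). For
  convex inclusions this equals the radial fraction; for mildly
  irregular shapes it degrades gracefully.
* **Degenerate inputs** have explicit conventions: constant images
  cannot be thresholded (error); an empty bleached ROI means the bleach
  failed (error); a stain filling the whole inclusion yields an empty
  unstained core, reported as full penetration
  (`penetration = external_mean_distance`, the limit of the formula as
  the core shrinks onto the centroid); no stain anywhere yields
  core = inclusion (zero-penetration limit). Flat-stain cases are told
  apart by comparing the region's level to the rest of the image.
* **Exponential fits** use Levenberg–Marquardt with box constraints
  (`A` in [0, 2], `tau` positive); on fit failure the mobility summary
  reports the delta-based estimate flagged `fit_ok = FALSE`.
* **Log binning** uses half-open `[lo, hi)` bins with the last bin
  closed; zero or negative intensities cannot be log-binned and are
  excluded into a QC count.
* **Maturity band ties** (ratio exactly equal to a threshold) are
  INTERMEDIATE; classification uses strict inequalities on both sides.

# Design decisions that were genuinely open

* **Ratio orientation.** The classifier uses FlAsH:Cerulean with HBR =
  high ratio, consistent with the names Highly/Poorly
  Biarsenical-Reactive and with every reported worked example; the
  inverse orientation that appears once in prose is treated as a
  typographical inversion.
* **The pulse-shape gate** is reconstructed as a supervised linear
  discriminant calibrated per experiment, because the gate geometry of
  the original pulse-shape method is not restated in this workflow's
  description. The features are pulse shape at fixed area
  (`log width`, `log height − log area`); normalizing by area keeps
  expression level itself — which correlates with inclusion status —
  from driving a gate that is supposed to read shape. Equal class priors
  are forced so the gate is a boundary in shape space, not a prevalence
  guess inherited from calibration set sizes. Weakly separated
  calibration sets trigger a machine-readable separability warning.
* **FRAP ROI assignment** is frozen at the first post-bleach frame and
  reused across all frames; inclusions are treated as stationary over
  the 21-minute window (positions were re-imaged, not tracked).
* **Uniform profiles span the cell** (inclusion and cytoplasm at the
  same level) so that a fully mixed protein shows equal means in all
  three zones including the outer ring; segmentation channels use a
  cytoplasm level of 0 to provide the contrast automatic thresholding
  needs.
* **The maturity generator solves for the FlAsH level** that realizes a
  requested FlAsH:Cerulean ratio exactly in the noiseless limit
  (including the flat background's contribution to both means), so
  classification tests have exact ground truth. FlAsH-loss kinetics
  during amyloid conversion are not modeled; the ratio is a free
  parameter.

# Problem sizes used in validation

The shipped tests and the acceptance script validate on: 128×128 px
scenes (inclusion radii 15–40 px); FRAP series of 22 frames at 128×128
with 20 seeds (immobile) and 50 seeds per mobile fraction in
{0.3, 0.6, 1.0}; penetration grids over radii {15, 25, 40} × coat depths
{0, 2, 5, 10} px against a brute-force raster oracle; 100 seeded
shell-enrichment scenes; and cytometry populations of 50,000 events.
These sizes give binomial/Monte-Carlo error well inside the asserted
tolerances while keeping a full validation run in the order of a minute.

# Known limitations

* Single-cell, single-inclusion scenes; no crowded fields, no watershed
  separation of touching inclusions.
* 2D only; penetration and zones are planar measurements.
* No PSF/deconvolution modeling: measured penetration carries the 110%
  geometric floor and rasterization granularity (±1 px scale).
* FCS binary parsing is out of scope; CSV event tables are the
  interface.
* Statistical hypothesis-testing layers (repeated-measures ANOVA,
  multiple-comparison procedures) are delegated to standard tools; the
  package emits the tidy per-cell/per-bin tables those tools consume.

# A worked example

```{r example}
set.seed(1)
# a mature-looking inclusion: low FlAsH:Cerulean target
sc <- render_scene(scene_spec(flash_cerulean_ratio_target = 0.049,
                              background_level = 2, noise_sigma = 4, seed = 2))
roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
ratio <- flash_cerulean_ratio(
  mean_intensity(get_channel(sc$image, "flash"), roi),
  mean_intensity(get_channel(sc$image, "cerulean"), roi)
)
thr <- maturity_thresholds(mean = 0.063, sem = 0.002)
data.frame(ratio = round(ratio, 3),
           label = as.character(classify_maturity(ratio, thr)))
```
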