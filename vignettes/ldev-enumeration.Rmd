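---
title: "Counting leukocyte-derived extracellular vesicles in blood images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting leukocyte-derived extracellular vesicles in blood images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcounter)
```

## The assay and its model

Whole blood is labelled with a nuclear dye (Hoechst/DAPI) and antibodies
against CD45 (leukocytes), CD61 (platelets) and CD235a (erythrocytes),
diluted 500×, and 10 µL of the dilution — 0.02 µL of blood — is loaded
into a counting-chamber well imaged as 55–65 frames per channel with a
10×/0.45 NA objective (0.64 µm/pixel). Four object classes are then
enumerated from the images: nucleated CD45+ leukocytes (7–20 µm),
anuclear CD45+ ldEVs, CD61+ platelets (2–5 µm) and CD235a+ red blood
cells (6–10 µm). In the EpCAM-enriched variant the full 7.5 mL of a blood
tube passes through immunomagnetic enrichment; leukocytes and ldEVs are
EpCAM-negative, so only a tiny carried-over fraction reaches the cartridge.

`evcounter` reproduces this as four composable stages — simulation,
detection, gating, quantification — with per-class counts per well as the
central currency.

## Detection and measurement

Each channel of a frame is thresholded at `background + k·σ` with `k = 5`
by default; the background and noise σ are the median and scaled MAD
(1.4826·MAD) of the frame, estimated on a deterministic subsample of at
most 2^16 pixels (relative standard error below 1%). A Gaussian low-pass
background is available for frames with illumination gradients. The union
of the per-channel masks is labelled into 8-connected components
(4-connectivity is available) and components of four pixels or fewer are
discarded — objects must be *strictly* larger than four pixels. There is
deliberately no watershed splitting: clusters of touching cells segment as
one object, which is a documented behaviour of this assay class (it
motivates removing the leukocyte size cap on enriched cartridges), so the
package reproduces rather than "fixes" it.

Per object and channel we record mean, max, min, standard deviation and
integrated intensity on background-subtracted pixels; morphology is shared
across channels: size in µm² (`area_px · 0.64²` at the default pitch),
edge-count perimeter in pixels, eccentricity from the second central
moments of the pixel set (the fitted-ellipse `√(1−(b/a)²)`), roundness
`4π·area/perimeter²` and the equivalent circular radius `√(size/π)` —
which maps the 9 µm² minimum observed object area to a ≈1.7 µm disc.
The gates only consume the mean/max/std intensities and the size,
perimeter and eccentricity; the remaining measurements round out a
standard ten-feature cytometry panel and cannot change any gated count.
Whether intensities should be background-subtracted before gate comparison
is not externally fixed; we subtract, and calibrate the synthetic
intensities so that gated positives clear their thresholds either way
(see below).

## Gating

A gate is a conjunction of criteria `feature <cmp> threshold` with `>`
strict and `≤` inclusive, exactly as printed in gate tables. The two
bundled libraries are bit-exact JSON transcriptions of the published gate
set: library B (whole blood) defines all four classes; library A
(EpCAM-enriched) defines leukocytes (without the ≤400 µm² CD45 size cap)
and ldEVs, with cytokeratin negativity replacing the CD61/CD235a criteria.
Negativity is operationalised as "standard deviation ≤ 5" on a channel,
including a noise-only *extra* channel that both the generator and the
detector always carry. Gates reference channel *roles* (`nuclear`, `CD45`,
…); a channel map ties roles to concrete channel names (DAPI in library A,
Hoechst in B). The one printed size cell without units (ldEV size ≤150 in
library A) is read as µm², matching its paired cell in library B.

Objects matching several gates are reported `ambiguous`, never assigned by
priority; unmatched objects are `unclassified`. Totals are conserved by
construction, and on ideal synthetic wells ambiguity is zero because a
bright channel always has edge pixels, hence `std > 5`.

## The synthetic generator

The generator is the package's substitute for the study's unreleased image
sets, and its defaults are the study conditions: 500× dilution, 10 µL
loaded (0.02 µL blood/well), 60 frames/well, 4–6 technical replicates
(default 5), 0.64 µm pixels. Default concentrations are typical adult
hematology values — leukocytes 4,500/µL, RBCs 5×10⁶/µL, platelets
2.5×10⁵/µL — plus 1,500 ldEVs/µL; the one externally reported number, 900
ldEVs/µL in healthy donors, is used explicitly in the acceptance checks.
The ldEV diameter default (1–6 µm) is a free modelling parameter: their
true size distribution is unresolved at this pixel pitch, and the smallest
ldEVs fall below the four-pixel detection floor exactly as they do in the
real assay.

Per well, each population contributes `Poisson(concentration × volume ×
retention)` particles, placed uniformly over frames and frame area with
uniform diameters. Settled classes (leukocytes, RBCs) render in focus;
suspended small objects (ldEVs, platelets) draw a defocus σ uniform in
0–2 px, reflecting that they float above the focal plane and appear
blurred and enlarged — a per-particle Gaussian blur of the rendered disc.
Rendering is an anti-aliased disc (4×4 subpixel coverage) convolved with
that Gaussian and normalised so the *post-blur peak* equals the particle's
marker intensity: expression levels map to peak intensities 0 / 40 / 120
(negative / low / positive) above a background of 100 with noise σ = 2.
This is the only calibration the problem fixes: "positive" must clear the
mean > 30 and max > 50 gates after background subtraction at any defocus,
"low" straddles them, "negative" contributes nothing beyond noise. Peak
normalisation deliberately sacrifices flux conservation under blur — the
alternative (energy conservation) makes strongly defocused vesicles
undetectable, which contradicts the assay's observation that out-of-focus
EVs are detected with inflated perceived size.

The EpCAM-enriched mode multiplies concentrations by per-class retention
probabilities (defaults: leukocyte 10⁻³, ldEV 5×10⁻⁴, platelet and RBC 0)
— a single-parameter stand-in for plasma-fraction loss, Fc-receptor
carry-over and excitation differences, none of which are quantified
individually — and can place a configurable fraction of leukocytes within
touching distance of another leukocyte to emulate cartridge clustering.
Interactions beyond that are deliberately absent: placement is uniform and
classes independent.

What the generator does **not** emulate: physical point-spread functions
(exposure times are metadata only), spectral bleed-through, illumination
gradients (available in the detector but not the renderer), RBC
aggregation/rouleaux, the CD45-dim granulocyte subpopulation, or
autofluorescent debris. Passing tests therefore demonstrate that the
*computational chain* is correct and self-consistent — not that it would
reproduce absolute counts on real images, where those effects caused the
reported systematic undercounting relative to a hematology analyzer.

## Quantification

Counts extrapolate linearly with volume (`count × target/sampled`,
reported unrounded): 18 ldEVs in 0.02 µL is 900/µL, or 6.75×10⁶ per
7.5 mL tube. The relative frequency is reported as leukocytes-per-ldEV
("one ldEV per three leukocytes" = 3) and is undefined — `NA`, not
infinity — when no ldEVs were counted. Replicate statistics use the
sample SD and `SE% = 100·(SD/√n)/mean`; averages of SE% across donors are
plain means, matching the convention "an average standard error of X%".
Box-plot summaries use linear-interpolation quartiles (`quantile type 7`,
recorded in the output, since only the whisker formulas are externally
fixed) with fences `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR`. Correlation against
reference counts is an ordinary least-squares fit on per-donor means
(replicates averaged first), with `R² = 1 − SSres/SStot` and a per-class
underestimation factor `mean(imaging)/mean(reference)`.

## Numerical choices and degenerate inputs

* Coordinates are 0-based row/col with pixel centres at integers; areas
  are pixel counts, sizes `area × pitch²` exactly.
* A constant frame has noise σ = 0; the threshold then falls back to
  `background + 1` so saturated-flat inputs still segment.
* Single-pixel objects have `std = 0` and eccentricity 0 by convention
  (they are normally removed by the four-pixel filter anyway).
* The per-well RNG is derived from (config seed, well index) and the
  caller's RNG state is restored afterwards; identical configs give
  bit-identical ground truth. Frame noise comes from a compiled
  splitmix64 + Box–Muller generator seeded from the R stream, so renders
  are reproducible too.
* An expected per-well count above 10⁶ (configurable) raises an error
  rather than silently simulating an implausible well.
* Particles whose centre leaves the frame are rendered clipped and
  flagged `clipped` in the ground truth; border objects are kept by
  default (`border_policy = "exclude"` drops them) because frames tile a
  whole well.

## Problem sizes used in the checks

The validation experiments are sized to be decisive yet quick: Poisson
statistics use 200–400 simulated wells (Monte-Carlo tolerance of three
standard errors); recovery experiments use 256×256 frames at densities
where overlap-induced merges are countable from the ground truth; the
ratio-recovery cohort uses 4 donors × 3 wells × 40 frames; and one
cohort-scale run exercises 10 donors × 5 wells × 60 frames of 512×512
across all five channels at full physiological concentrations. At that
frame geometry whole blood is far denser per frame than in the original
chamber (whose sensor covers ~16× more area per frame), so its counts are
dominated by merged objects; the run validates throughput and stability,
while the correctness claims come from the geometry-matched recovery
experiments.

## Known limitations

* Segmentation reproduces the merge-clusters-into-one-object behaviour;
  counts are therefore biased low at high densities, as in the assay.
* The enrichment model is a net-effect Bernoulli retention; it makes no
  claim about the mechanism split, and the 1:5 vs 1:6 distinction between
  patient groups is outside what the model can address.
* Eccentricity from discrete pixel moments is biased for objects a few
  pixels across; the gates' 0.85 cap is tolerant to this at the sizes
  that pass the four-pixel filter.
* No bright-field channel: ldEVs are reported invisible in bright field,
  so the package does not model it.
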