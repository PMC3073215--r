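---
title: "Counting FISH probe signals and scoring HER2 amplification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting FISH probe signals and scoring HER2 amplification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishdots)
```

## The problem

In the two-probe FISH assay for HER2 status, tumour nuclei are counterstained
with DAPI (blue), the HER2/neu gene is tagged with a probe that fluoresces
red/orange, and the centromere of chromosome 17 is tagged with a green
CEP17 probe. Each probe copy appears as a small bright dot. A case is scored
by counting, per nucleus, the red and green dots, forming the per-nucleus
ratio HER2/CEP17, and averaging the ratio over a target of 60 scorable
cells. The mean ratio is then read against decision bands: above 2.2 the
case is amplified, below 1.8 it is non-amplified, and the closed interval
[1.8, 2.2] is equivocal and needs further work-up. `fishdots` automates this
read-out with two independent dot-detection engines so that their scores can
be compared nucleus by nucleus on the same segmentation.

## Pipeline

1. **Channel handling** (`read_rgb()`, `split_channels()`). Images are read
   from 8- or 16-bit TIFF or PNG; all analysis runs on intensities
   normalized to [0, 1], so every downstream parameter is bit-depth
   agnostic. Pixel coordinates are 0-based (row, column).
2. **Nucleus segmentation** (`segment_nuclei()`). The blue channel is
   median-smoothed (radius 2 px), thresholded with Otsu's method (both
   parameter-free and reproducible; the scoring protocol itself prescribes
   no method), holes are filled, and touching nuclei are split by a
   watershed on the negated Euclidean distance transform. Watershed markers
   are depth-suppressed maxima of the distance map (depth 0.1 of its
   maximum by default) rather than raw regional maxima, which would
   over-segment rasterised discs. Objects are then gated on area
   (500-50,000 px), solidity (>= 0.85), eccentricity (<= 0.95) and border
   contact — a border-clipped nucleus cannot guarantee complete dot content,
   so it is dropped, which is standard FISH-scoring practice. Survivors are
   re-indexed in raster order of their centroids so reports are
   deterministic. The shape gates were tuned on the synthetic fixtures
   described below and are all configurable.
3. **Dot detection**, with either or both engines (below).
4. **Scoring** (`nucleus_scores()`, `case_score()`, `classify_ratio()`).
   Dots belong to the nucleus containing their centroid. A nucleus without
   any green dot has an undefined ratio and is excluded (at least one CEP17
   copy is biologically expected; a zero denominator signals a detection
   failure). The case mean is the mean of per-nucleus ratios — "averaging
   the scores" — over the first 60 scorable nuclei; the ratio of summed
   counts is available as an alternative mode since the two differ under
   copy-number heterogeneity. Boundary ratios 1.8 and 2.2 fall in the
   equivocal band; strictly outside it the classification is
   non-amplified/amplified.

## The morphological engine

The top-hat of an image `I` with respect to a flat structuring element is
`TH = I - opening(I)`; the bottom-hat is `BH = closing(I) - I`. `TH`
extracts bright details smaller than the structuring element from an uneven
background; `BH` extracts the corresponding dark details. The enhancement
used here combines them:

```
E = clip(I + TH - BH, 0, 1)
```

so small bright details are pushed toward white and the surrounding texture
toward black, while background unevenness cancels. Clipping makes the
implied saturation explicit. The structuring element is a flat disk of
radius 5 px by default: dots in the fixtures span roughly 3-9 px, and the
element must be larger than any dot it should enhance. All morphology uses
symmetric (edge-inclusive mirror) border padding; this is part of the
contract and the oracle tests reproduce it exactly.

Detection then thresholds `E` *inside each nucleus separately* (Otsu within
the nucleus mask by default, a mean-plus-k-sigma rule as an alternative):
nuclei differ in background level, so a global cut would trade false
negatives in bright nuclei against false positives in dim ones. A nucleus
whose enhanced intensities span less than `min_contrast` (default 0.1) is
declared dot-free rather than letting Otsu split pure noise. Connected
components with area in [2, pi * 25] px become dot records; anything outside
every nucleus is never a dot.

## The inverse multifractal engine

For each pixel, a local measure `mu_eps` is accumulated over centred windows
of width `eps` in {1, 3, 5, 7} — by default the **sum** of intensities, the
usual intensity measure in inverse multifractal image analysis (max and min
are provided for experimentation). The Hoelder exponent `alpha(i, j)` is the
least-squares slope of `log mu_eps` against `log eps`; a floor of 1e-12 on
the measure keeps the logarithm finite on dark regions. For a constant
image the sum measure scales exactly as `eps^2`, so `alpha = 2` — the
embedding dimension — which the tests verify to 1e-9.

The spectrum `f(alpha)` is estimated by the histogram method: the observed
alpha range is split into 100 equal bins; for each bin, the pixels in it
are box-counted over dyadic grids (`delta` in {1, 2, 4, 8, 16}, grid
anchored at the origin, partial boxes included), and `f` is the slope of
`log N_delta` versus `log(1/delta)`. Empty bins get `f = 0` by convention.
The per-pixel spectrum image is `f(i, j) = f(alpha(i, j))`. The spectrum is
computed over the whole image, not per nucleus: `f` measures how *rare* an
exponent is in the global structure.

A bright dot makes the windowed sum nearly scale-constant at its centre, so
under the sum measure dots have `alpha` *below* the background value 2 —
local singularity — while their exponents occupy sparsely-populated bins —
global rarity, low `f`. `inverse_select()` therefore keeps pixels with
`alpha` strictly below the 2nd percentile of the alpha distribution *and*
`f <= 1`. Conventions that measure irregularity the other way round put
dots in the high tail, so `alpha_tail = "high"` (selecting at or above the
percentile — with percentile 0, the whole image) is exposed in the
configuration. Selected pixels inside nuclei are grouped into connected
components and area-gated like the morphological engine, except that the
minimum component area is 5 px: a percentile-tail selection unavoidably
admits a few isolated noise pixels, and on the fixtures their clusters
(1-4 px) are an order of magnitude smaller than the selected core of a
resolved dot (8-14 px at dot width sigma = 1.5 px). Both the percentile and
the area gate were calibrated once on the synthetic fixtures and then
frozen; they are deliberate, documented choices, not protocol constants.

## The synthetic generator

No clinical FISH images ship with the package, so validation rests on
`generate_case()`: seeded, bit-reproducible synthetic cases with exact
ground truth. A default case is a 600 x 600 px 16-bit image with 20
elliptical nuclei (major semi-axis 24-32 px, axis ratio sampled in
[1, 1.4] to exercise the eccentricity gate, no mutual overlap, none
touching the border), filled at intensity 0.7 with 12% multiplicative
texture. Probe dots are isotropic Gaussians (sigma 1.5 px, peak 0.8 over a
0.1 background, truncated at 4 sigma), placed inside their nucleus with at
least 9 px same-channel separation so that ground-truth counts are
unambiguous; additive Gaussian noise (sigma 0.02) is applied to every
channel before clipping and 16-bit quantisation. Two failure modes are
modelled: `no_dapi = TRUE` leaves the blue channel at the noise floor, and
`overlap_fraction` renders that share of red dots at 1.5 sigma from an
existing red dot, merging them into one component as happens with
clustered HER2 signals in amplified tissue.

What the generator does *not* emulate: optical point-spread blur and
chromatic aberration, photobleaching, autofluorescence texture in the probe
channels, partially overlapping or clustered nuclei beyond simple contact,
z-stack effects, and cross-channel bleed-through. Passing the synthetic
round-trips therefore demonstrates correctness of the algorithms under
their stated model — bright compact dots in well-stained nuclei — not
clinical-grade accuracy on real slides.

## Failure modes and QC

`qc_dapi()` flags a case as "no DAPI suspected" when retained nuclei cover
less than 1% of the image or the 99th-percentile blue intensity is below
0.05. A flagged image contributes no nuclei; if a whole case ends up with
zero scorable nuclei, scoring raises a classed error
(`fishdots_unscorable`) that carries the QC context, and the command-line
tool exits non-zero with an explicit unscorable report. Dots are never
scored outside nuclei — on a no-DAPI image the red channel may be full of
signals, and silently counting them would fabricate a ratio.

Merged red dots are undercounted by design (one component, `est_count = 1`).
`estimate_count()` optionally divides a component's area by the median
green-dot area and rounds (floor 1). On fixtures with half the red dots
overlapping, this moves the case mean from about 1.0 to about 1.7 against a
truth of 2.0: the bias shrinks but does not vanish, which is why the
estimator is off by default and clearly labelled a naive extension; proper
resolution of merged signals needs dedicated post-processing.

## Numerical choices and edge cases

- All windowed and morphological operators use symmetric edge-inclusive
  mirror padding; tests hold the implementation to exact (bit-level)
  agreement with brute-force sliding min/max oracles under that policy.
- Connected components use 4-connectivity throughout.
- A blank blue channel returns an empty segmentation with a warning, not an
  error; a degenerate alpha range collapses the spectrum to a single bin;
  a structuring element larger than the image is a parameter error.
- Relabelling, dot ordering and report serialisation are deterministic;
  identical seeds and configurations reproduce images, label maps and
  report files bit for bit.
- The protocol texts disagree on the decision rule: a shorthand "ratio of
  2.0 denotes amplification" versus the 1.8/2.2 bands. The bands are
  implemented; under them a reported ratio of 2.02 or 2.14 is equivocal
  even though it exceeds 2.0, and 2.22 (just above the band edge) is
  amplified.
- Problem sizes used by the validation suite and the acceptance script —
  100 random 16 x 16 images for the morphology oracle, 256 x 256 analytic
  spectrum fixtures, 64 x 64 exact box-count comparisons, and 20-nucleus
  cases (100 noise-free nuclei for the exactness rate) — were chosen as the
  smallest sizes at which the asymptotic properties are already clean.

## Known limitations

- Shape gates and detector defaults are fixture-tuned; clinical material
  will need recalibration against a pathologist's reading.
- The naive area estimator cannot separate three-fold or denser HER2
  clusters reliably; polysomy of chromosome 17 is not called.
- Learning-based nucleus segmentation is out of scope; heavily clustered
  or poorly stained nuclei will be dropped by the shape gates rather than
  rescued.
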