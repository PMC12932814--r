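---
title: "Evaluating copper chloride crystallisation fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating copper chloride crystallisation fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccfp)
```

## The method and its statistical question

Copper chloride crystallisation (CCC) evaporates a mixture of a plant
extract and CuCl~2~ solution on a glass plate, producing a ramified
dendritic crystal pattern — the *fingerprint* — whose morphology reflects
the composition of the sample. `cccfp` implements the computational half
of a CCC sensitivity study on mistletoe (*Viscum album*) extracts: image
analysis that condenses each fingerprint into a handful of texture and
structure variables, a systematic-control-driven block randomisation of
plates to chamber positions, and a three-tier statistical evaluation that
asks whether the fingerprints discriminate

1. mistletoe **subspecies** (subsp. *album*, VAA, on apple and oak vs
   subsp. *austriacum*, VAAu, on pine) — all 288 plates;
2. **deciduous host trees** (apple vs oak) within VAA — the 192 VAA
   plates;
3. **blending procedures** (machine vs hand blending of the winter and
   summer harvest juices) — all 288 plates.

The laboratory scans themselves are not distributed, so the package ships
a synthetic fingerprint simulator that reproduces the *statistical
structure* of the experiment. Every pipeline stage can therefore be
exercised, and its operating characteristics measured, without any
external data.

## The experimental design

The full Verum design is 6 experimental days × 2 crystallisation chambers
× 6 samples per chamber × 4 technical replicates = 288 fingerprints, 48
per day. Each chamber carries one production batch (chamber 1 → 2109,
chamber 2 → 2204), and the 6 samples per chamber are the crossing of 3
host trees with 2 blending procedures, giving 12 stock solutions per day.
The subspecies is not a free factor: it is determined by the host tree
(pine → VAAu, apple/oak → VAA).

```{r design}
design <- build_verum_design()
nrow(design)
table(design$day)[1]
nrow(sensitivity_subset(design, "deciduous")$design)
```

Samples are coded with blinded letters (A–F, G–L per chamber); the factor
columns carried in the design table play the role of the decoding map,
which in the original workflow is applied only at the statistics stage.

A chamber holds 43 physical positions in two concentric rings, of which
24 are used for the randomised samples. Which 24 of the 43 were used is
not recoverable from the study description, so the layout keeps the used
subset configurable and defaults to the first 24 positions.

## Image analysis

**Texture.** A grey-level co-occurrence matrix (GLCM) is accumulated over
one-pixel horizontal and vertical offsets inside the full-plate region of
interest (ROI 0–100% of the plate radius), symmetrised, and normalised.
Fifteen second-order variables are computed from it. The study names only
four of them, which we define as:

* `entropy` $= -\sum_{ij} p_{ij}\ln p_{ij}$ — randomness of the
  grey-level pair distribution (natural log; the log base is a scale
  choice only);
* `cluster_shade` $= \sum_{ij}(i+j-\mu_x-\mu_y)^3 p_{ij}$ — skewness /
  asymmetry of the pattern;
* `diagonal_moment` $= \sum_{ij}|i-j|\,(i+j-\mu_x-\mu_y)\,p_{ij}$ — a
  sign-carrying roughness measure, positive when bright areas are rough
  and dark areas smooth;
* `kappa` $= (P_o-P_e)/(1-P_e)$ with $P_o=\sum_i p_{ii}$,
  $P_e=\sum_i p_{x,i}\,p_{y,i}$ — chance-corrected diagonal agreement,
  a consistency measure.

The exact formulas behind the original software's `kappa` and
`diagonal_moment` are not printed anywhere accessible, so the definitions
above are this package's own, chosen to satisfy the documented
interpretations (sign convention of `diagonal_moment`; `kappa` as an
agreement coefficient in $[-1,1]$). The remaining 11 variables are the
standard Haralick second-order set, so the documented count of 15 texture
variables is honoured and the correlation-filter stage has a realistic
pool. Grey levels are quantised linearly from 8 bits to 32 levels by
default — the original level count is unstated; 32 keeps a plate-sized
ROI's matrix well populated while remaining sensitive to speckle.

**Structure.** Needle morphology is measured at ROI 0–90%: the image is
binarised by an adaptive local-mean threshold (window = plate radius / 8,
computed over ROI pixels only, which makes the segmentation robust to
smooth illumination gradients), thinned to a one-pixel skeleton
(Zhang–Suen), and decomposed into *needles*: maximal skeleton paths
between nodes (endpoints or branch points). Three variables enter the
analysis:

* `lend` — the number of skeleton endpoint pixels (degree-1 pixels);
* `l220` — needles with step-sum length in $[19.2, 22)$ px;
* `l250` — needles with length $\ge 22$ px.

Lengths are the sum of inter-pixel steps (1 orthogonal, $\sqrt 2$
diagonal). Only the two uppermost length-bin edges (19.2 and 22 px) are
documented; the other 13 bins follow one geometric convention with ratio
$r = 22/19.2$ descending from 19.2 px, so all bins share the same
relative width as the two printed edges. Widths (twice the Euclidean
distance transform averaged along each needle) are histogrammed
analogously. Segments shorter than 2 px are pruned before binning: raster
thinning necessarily leaves tiny spur and junction artefacts, and on
jagged rasterised curves small redundant segments between nearby
branch-point clusters are unavoidable; the pruning threshold is
configurable.

**Variable pool.** Of the 15 + 15 measures the analysis retains 7:
`kappa`, `diagonal_moment`, `entropy`, `cluster_shade`, `lend`, `l220`,
`l250`, after a correlation filter (`correlation_filter()`) that greedily
removes one member of any pair with $|r| > 0.7$ — the member with the
larger mean absolute correlation to the remaining pool.

## Randomisation from systematic controls

Systematic-control (SC) runs crystallise a single extract in every used
position, over three days per chamber. After dividing each value by its
(variable, day) mean — which makes days and differently scaled variables
commensurable — candidate partitions of the 24 positions into 6 blocks of
4 are drawn at random (2 million in the original procedure;
`search_schemes()` draws them sequentially from one seed, so shorter
searches are prefixes of longer ones and the best score is monotone in
the search size). Each candidate is scored by the mean over the 7
variables of the SD of its 6 block means; whether the original scored raw
or normalised data, and aggregated by mean or maximum, is unstated, so
both are options (`normalise`, `aggregate`). The final scheme is the
best-scoring candidate for which one-way ANOVAs of all 7 variables across
the 6 blocks show no location effect (all $p > \alpha$; the original
states only "no statistically significant differences", so $\alpha$
defaults to the conventional 0.05). Samples are then rotated through the
blocks across the 6 days as a Latin square (`build_rotation()`, a
random row/column/symbol permutation of the cyclic square — deterministic
per seed, though not uniform over all Latin squares, which is immaterial
for counterbalancing).

## Statistical evaluation

Each sensitivity test fits, per variable, a four-way fixed-effects ANOVA
with main effects and all two-way interactions, using sum-to-zero factor
coding. The four factors are day, batch, blending and the factor of
interest (subspecies; deciduous host; blending — in the third test the
remaining factor is the host tree). Chamber is aliased with batch by
design and must not enter the model. Because the subspecies test pools
apple + oak against pine (192 vs 96), the layout is unbalanced in the
factor of interest; Type-II sums of squares keep the main-effect tests
interpretable there and coincide with sequential sums of squares in the
balanced tests (a tested invariant). Day is treated as fixed — the study
analyses those six specific days rather than a day population.

Pairwise comparisons use the protected Fisher LSD: they are computed only
when the preceding F-test is significant at the study's threshold
$p < 0.01$ (two-sided throughout). Effect sizes are Cohen's
$d = (\bar x_a - \bar x_b)/s_{\text{pooled}}$ on the raw (not
day-normalised) values, pooled over all other factors — the original
computation is unstated, and this pooled convention is the one whose
recovery the synthetic calibration verifies; it is exposed as the single
place effect sizes are computed (`cohens_d()`). Interactions of the
factor of interest reaching $p < 0.01$ are flagged with the compact
letter codes d/b/p/h (day, batch, blending procedure, host tree) used in
the study's summary table, and a flagged day interaction triggers a
per-day drill-down that reports on which experimental days the contrast
is individually significant. A saturated fit with zero residual variance
reports the sentinel $F=\infty$, $p=0$ rather than failing, so degenerate
fixtures remain analysable.

## The synthetic generator

**Direct mode** (`generate_feature_table()`) draws the 7 variables from
the linear model
$$y = \mu_v + \textstyle\sum_f c_f\, d_f\, \sigma + a_{\text{day}} +
a_{\text{batch}} + \varepsilon,\qquad \varepsilon\sim N(0,\sigma^2),$$
where $c_f = \pm\tfrac12$ is the contrast sign of the plate's level on
factor $f$ (VAA − VAAu, apple − oak with pine at 0, machine − hand,
batch 2109 − 2204) and $d_f$ the specified standardised effect. A target
with effect $d$ therefore separates its two groups by exactly
$d\,\sigma$, so the recovered Cohen's $d$ is directly comparable to the
specification. Baseline means are arbitrary location constants (they
cancel from every statistic used); the defaults are round numbers of
plausible magnitude for each variable.

**Image mode** (`generate_image_set()`) applies the same effect grammar
to the latent growth parameters of the simulator: needles grow from
radially oriented seeds near the plate centre as random walks with small
angular diffusion, branching with a per-step probability at a fixed
relative angle (≈0.6 rad) plus jitter; needle length is lognormal with
mean `length_scale`. This growth model was chosen over
diffusion-limited aggregation because it exposes a *direct* length
parameter, which is what the structure variables measure. Rendering
stamps anti-aliased discs along each walk, applies multiplicative
lognormal speckle (so the texture variables respond to `texture_grain`)
before 8-bit quantisation, and forces everything outside the plate disc
to the background level. Contrasts and day/batch offsets act additively
on the log of the targeted parameter, with per-plate lognormal latent
noise of SD `residual_sigma`; on the log scale a standardised difference
remains interpretable for positive-valued parameters. Each plate draws
from its own child seed of the master seed, so enlarging a design never
perturbs existing plates, and identical inputs reproduce bit-identical
images.

The simulator emulates the *statistical* features the pipeline assumes —
factorial group differences, additive day/batch shifts, measurement
noise, centre-grown ramified bright structures on a speckled plate. It
does not emulate evaporation physics, nucleation chemistry, colour, ring
artefacts, or the visual gestalt of real fingerprints, and no
quantitative morphology of real plates is available to tune it against.
Passing tests therefore demonstrate that the *pipeline* is correct and
well calibrated under the stated model, not that real fingerprints carry
the effects.

## Numerical and calibration choices

* **Problem sizes.** The effect-size calibration uses the experiment's
  group sizes (192 vs 96, 96 vs 96, 144 vs 144) with unit residual SD and
  the study's reported effects (1.76, 0.57, 0.28), averaging the
  recovered $d$ over 200 replicates; its Monte-Carlo standard error is
  then ≈0.01, an order of magnitude below the smallest reported effect.
  Randomisation searches default to the original 2,000,000 candidates but
  are exercised with 10^2–10^3 candidates in the test profile — the
  nested-prefix property makes the two regimes directly comparable.
* **Reduced designs.** A sensitivity test on a design where a nuisance
  factor collapses to one level (e.g. a single-day pilot run) drops that
  factor from the model with a warning; a single-level factor of
  interest is an error.
* **Ties and degenerate inputs.** Constant-data searches score every
  candidate 0 and return the first; constant feature columns are dropped
  from the correlation filter with a warning; a single-grey-level GLCM
  defines `kappa = 0` with a warning; an empty binarisation yields
  all-zero structure features with a warning rather than an error.
* **Bin conventions.** All histogram bins are right-open $[lo, hi)$
  except the top bin; a needle of length exactly 22 px is therefore an
  `l250` needle, not `l220`. The two printed edges are pinned exactly
  (no floating-point drift from the geometric construction).
* **ROI convention.** Percentages are fractions of the plate radius from
  the centre; the annulus is closed at the inner and open at the outer
  bound.

## Known limitations

* The skeleton of a rasterised curve is 8-connected but not minimal:
  junction clusters and 1–2 px redundant segments occur, which is why
  segment pruning exists and why `lend` (endpoint pixels) is preferred to
  segment-end counting.
* The headline biological findings of the original study cannot be
  reproduced here: the raw scans are not public. What the package
  reproduces exactly are the design identities and variable definitions;
  what it reproduces statistically is the recovery of the reported effect
  sizes under the synthetic model at the original group sizes.
* Day is fixed, not random; no mixed-model or multiple-testing machinery
  beyond the protected LSD and the 0.01 threshold is provided, matching
  the evaluated procedure.
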