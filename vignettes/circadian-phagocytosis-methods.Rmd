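---
title: "Methods: circadian analysis of phagocytosis and proteoglycan rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian analysis of phagocytosis and proteoglycan rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphage)
library(dplyr)
```

`circaphage` turns two kinds of raw circadian measurements — per-cell
fluorescence from microscopy of macrophages fed labelled amyloid-beta, and
LC-MS-derived disaccharide concentrations of heparan/chondroitin sulfate
proteoglycans — into rhythm verdicts and effect-size-gated group
comparisons. This vignette explains the models, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the known limitations.

## The oscillator model

Every rhythm question in the package reduces to fitting the extended
harmonic oscillator (a damped cosine with an offset):

$$\hat y(t) = A\, e^{-\gamma (t - t_0)} \cos\!\left(\frac{2\pi (t - t_0)}{\tau} + \phi\right) + C$$

* `A` — amplitude, in the data's units (log10 intensity or ng/cell); `A = 0`
  is the constant model.
* `gamma` — amplitude-change (AC) coefficient in h⁻¹. Zero means a sustained
  oscillation; positive damped, negative forced. The circadian gate uses
  |γ| ≤ 0.15 h⁻¹, inclusive. The threshold's units are a package decision:
  with the decay applied as `exp(-gamma * (t - t0))` and `t` in hours, γ is
  in inverse hours.
* `tau` — period in hours; the circadian window is 18–30 h.
* `phi` — phase in radians, reported in `[0, 2π)`; `t0` is the first
  observation time, so phase anchors to the start of the recording.
* `C` — equilibrium (midline) level.

`fit_eho()` minimizes the sum of squared errors over *all* observation
points with Levenberg–Marquardt least squares (`minpack.lm`), from a
multi-start grid: τ ∈ {18, 20, …, 30}, φ ∈ {0, π/2, π, 3π/2},
γ ∈ {−0.1, 0, 0.1}, with `A0 = (max − min)/2` and `C0 = mean(y)`, plus a
constant-model start (`A = 0`). Including the constant start guarantees the
reported SSE never exceeds the best constant model's, so the oscillator
never looks worse than "no rhythm". Optimizer tolerances are fixed
(`ptol = 1e-8`, at most 200 iterations / 2000 evaluations per start).

### Period aliasing and its tie-break

Sampling every Δ hours makes the period non-identifiable across aliases: on
a 4-h grid an oscillator with τ = 4.8 h passes through exactly the same
gridpoint values as one with τ = 24 h, so the two SSE minima tie to
numerical precision. Rhythm tools resolve this with a period search range;
`fit_eho()` does the equivalent at selection time: among converged starts
whose SSE is within a 10⁻⁴ relative band of the minimum, it prefers a period
inside the criteria window, otherwise it takes the numerical minimum. The
period itself stays unconstrained during optimization (free run), which is
what lets flat-noise series wander out of the circadian window and fail the
period gate rather than being squeezed into it.

### The fit p value

The default goodness-of-fit test is a one-sided Kendall rank correlation
between fitted values and observations across all points: it asks whether
the fitted shape and the data rise and fall together, is exact for small n
without ties, and returns p = 1 for degenerate cases (constant fit, constant
data, fewer than 4 points). Because the fit is optimized on the same data it
is then correlated with, this test is anticonservative in isolation — on
pure noise most raw p values clear 0.05. Calibration comes from the *joint*
gate: a circadian call also requires the period window, the AC window, and
BH- and BY-adjusted p values (adjusted across every series fitted in the
same call) below α = 0.05. Under that full gate, 200 flat-noise series at 13
timepoints yield ≤ 10 % false circadian calls (measured in the acceptance
suite). An F test of the oscillator against the constant model
(4 and n − 5 degrees of freedom) is available via
`pvalue_method = "ftest"` for users who want a per-series calibrated test.

### Detrending and smoothing

`preprocess_series()` removes a least-squares line over all points and can
smooth by shifting each timepoint's replicate mean to the centred
(1, 2, 1)/4 moving average of adjacent timepoint means (endpoints
renormalize over the available neighbours); replicate deviations are
preserved so replicate-resolved fitting still works afterwards.

Both switches default **on** in the catalog wrapper `fit_rhythms()` — the
free-run-with-detrend-and-smooth convention appropriate for long
multi-cycle recordings such as luminescence traces. They default **off** in
the low-level `fit_eho()`, and the package's own validation fits single-cycle
designs without them, for a measured reason: over a 24-h window a linear
detrend absorbs part of the cosine (biasing the period low), and (1, 2, 1)/4
smoothing at 7 timepoints attenuates and biases the period high. On 50
simulated triplicate series at the 7 × 4-h design, recovery of the true 24-h
period within ±2 h was 52 % with both on and 100 % with both off. For real
single-cycle data with a suspected baseline drift, detrend but don't smooth.

### Replicate handling

Two conventions coexist, both explicit: phagocytosis series are collapsed to
timepoint means before fitting (`collapse_replicates = TRUE`), while
proteoglycan series keep all four replicates as independent observations
(`species_rhythms()` never collapses). Collapsing suits per-cell data whose
within-timepoint spread is biological cell-to-cell variation rather than
measurement error of the timepoint mean.

## Image quantification

Cells are detected from the Sobel gradient magnitude: pixels above
`edge_threshold` (default 0.2) times the image's maximum gradient form the
edge ring, which is closed with a disc brush (radius 1 px), hole-filled, and
labelled into connected components. Touching cells are *not* split; a
component of area `a` is a clump of `ceiling(a / a_max)` cells, capped at 4,
and components below `a_min` or above `4 * a_max` are discarded. Because the
filled footprint carries a one-to-two-pixel boundary band, intensities are
measured over the footprint eroded by 2 px (`interior_erode`), which keeps
background-corrected means within 5 % of truth on synthetic scenes while
areas stay in footprint units. The default area window
(`a_min = 150`, `a_max = 460` px²) was calibrated once against the
generator's radius-10 discs, whose measured footprints for clumps of 1–4 are
408/789/1172/1553 px²; **real images need their own calibration**, which is
why the window sits in `segmentation_config()`.

Background is the mean of sub-threshold pixels under Otsu's bimodal split; a
constant image is its own background and is flagged as having no foreground.

## Per-cell statistics

`preprocess_intensities()` applies, in one pass: (1) remove values at or
below the background signal; (2) log10 the survivors; (3) per timepoint,
remove values outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` of that timepoint's
logged values, with type-7 (linear-interpolation) quantiles and fences
computed once, not iterated. Per-timepoint (rather than experiment-wide)
fences are a documented assumption: outlier filtering precedes per-timepoint
summaries, and a rhythmic signal would otherwise inflate the experiment-wide
IQR. A timepoint left with fewer than three values skips the IQR step and is
flagged. Every removed row carries exactly one removal flag, and survivors
are never altered beyond the log10 map.

Group contrasts combine Welch's unequal-variance t test (two-sided; the
sidedness is a package choice) with Hedges' g — the pooled-SD standardized
mean difference times the small-sample correction `1 − 3/(4(n1+n2) − 9)`,
appropriate for groups of unequal size. Effect bands on |g|: above 0.2
small, 0.5 medium, 0.8 large. The joint rule — significant iff `p < α` and
`|g| ≥ g_min` — has defaults α = 0.05 and `g_min = 0.5`; stricter analyses
use `g_min = 2.0`, and both are config knobs surfaced in reports.

## Proteoglycan normalization

Cell counts come from inverting the fluorescence standard curve
(`count = dilution · (F − intercept)/slope`, OLS fit, R² reported); negative
back-calculated counts clamp to 0 and are flagged, and cell-pellet amounts
divide by the count to give ng/cell while media/ECM amounts divide by sample
volume to give ng/ml. The `units` column guards against mixing the two in a
summary. Class totals sum over sulfation codes per sample; Z-scores
standardize each species' cross-replicate timepoint means with the sample
(n−1) SD — computing them on replicate means rather than pooled replicates
is the documented choice where the convention is unstated — and constant
rows return zeros with a flag. Species with no detected signal are excluded
from rhythm fitting but contribute zeros to totals.

## The synthetic generator

The generator exists so every stage can be validated against retained ground
truth. It emulates: round cells as hard discs of uniform interior intensity
(clumps as chains of tangent discs, so clump area ≈ clump size × cell area),
additive Gaussian pixel noise on a flat background, uptake intensity driven
by `max(0, rhythm_value(t))` with mean-preserving lognormal per-cell
dispersion (default `sdlog = 0.1` — a free fixture parameter, not an
estimate from any real dataset, since per-cell dispersion is unreported),
4-h sampling from PS16 in triplicate (quadruplicate for glycans), HS/CS
series with circadian structure, and a near-linear fluorescence-vs-count
curve. Negative concentrations and intensities clamp to zero and the events
are counted.

It deliberately does **not** emulate realistic optics (point-spread
function, uneven illumination, bleed-through), 3-D stacks, cell motion, or
textured cells. Passing tests therefore demonstrate that the measurement and
inference machinery is correct under its stated assumptions — not that the
segmentation defaults transfer to real microscopy, which always requires
recalibrating the area window and edge threshold.

## Problem sizes used in validation

The package's own acceptance checks run: noiseless recovery on 25 points
over 48 h; 50 rhythmic series at the 7-timepoint triplicate design with
noise at 10 % of amplitude (≥ 80 % must be recovered circadian with τ within
±2 h); 200 flat-noise series of 13 timepoints (≤ 10 % false calls under
catalog-level BH/BY gating); 100 randomized oracle comparisons per statistic
at 10⁻¹⁰; 20 scenes with 240 cells (precision and recall ≥ 0.95, corrected
means within 5 %); and one end-to-end antiphase experiment whose
phagocytosis and HS-total zeniths must sit 12 ± 2 h apart. These sizes keep
the whole suite to a few minutes while leaving the pass thresholds
meaningful.

## Time bases

Three bases are used interchangeably: sample `index` (chronological order),
`PS` (hours post serum shock; index 0 is PS16) and `CT` (circadian time,
anchored so PS20 is CT8, i.e. CT = PS − 12, a constant offset consistent
with every printed PS/CT pair). Conversions are affine and round-trip
exactly; the anchoring of CT to external reference clock-gene data is out of
scope and consumed only as this fixed offset.

## Known limitations

* The fit p value is not the original ECHO tool's internal test; verdicts on
  real data may differ from that tool even where parameters agree, which is
  why validation targets recovery of generated ground truth rather than
  byte-level agreement.
* Clumps are never split into constituent cells; per-cell intensities from
  clumps are clump averages.
* The AC-coefficient bound is treated as inclusive and in h⁻¹; other
  conventions would shift verdicts for fits sitting exactly on the boundary.
* Catalog-level BH/BY means a series' verdict depends on what it was fitted
  with; fitting a series alone uses its raw p for all three gates.
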