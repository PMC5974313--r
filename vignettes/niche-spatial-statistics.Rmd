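---
title: "Quantifying niche clustering and cell proximity in tissue sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying niche clustering and cell proximity in tissue sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichespat)
```

## The question

During extramedullary hematopoiesis, mesenchymal stromal cells of the
spleen reorganize: reporter-positive niche cells that are scattered through
the red pulp at baseline accumulate in the perifollicular band of red pulp
that surrounds the white-pulp follicles, and hematopoietic stem/progenitor
cells (HSPCs) appear preferentially next to them. Two statistical
questions fall out of segmented 2-D cell coordinates:

1. **Clustering** — are the niche cells distributed non-randomly within an
   analysis window of red pulp?
2. **Proximity** — are HSPCs closer to niche cells than equally many
   random points of the same density would be?

`nichespat` answers both with resampling statistics against explicit
complete-spatial-randomness (CSR) nulls, and ships a synthetic
tissue-scene generator whose ground truth is known, so the statistics can
be calibrated and power-checked without microscopy data.

## The subsampled Hopkins statistic

For a pattern of $n$ points in a window $W$ (a rectangle minus circular
exclusion regions standing in for the white pulp), draw $m$ *sampling
origins* uniformly on the usable area and an $m$-point subsample of the
data without replacement. With $u_i$ the distance from origin $i$ to its
nearest data point and $w_i$ the distance from sampled data point $i$ to
its nearest *other* data point,

$$ H = \frac{\sum_{i=1}^m u_i^k}{\sum_{i=1}^m u_i^k + \sum_{i=1}^m w_i^k}. $$

Under CSR, origin-to-data and data-to-data nearest-neighbor distances are
exchangeable and $H$ concentrates near $0.5$; clustering shrinks the
$w_i$ and pushes $H$ toward 1, regularity pushes it below $0.5$. The
default exponent is $k = 1$ (`variant = "plain"`); the textbook
Hopkins–Skellam form for $d$-dimensional data uses $k = d = 2$ and is
available as `variant = "powered"`. Both variants are scale invariant and
bounded in $[0, 1]$; the degenerate all-coincident pattern gives exactly
$H = 1$ (and $0.5$ is returned in the measure-zero case where both sums
vanish).

The orientation deserves a note: some published implementations report
the complement $\sum w / (\sum u + \sum w)$, in which clustering gives
*small* values. Here $H > 0.5$ always means clustered, which matches how
indices around 0.58–0.61 for perifollicular accumulation versus ~0.5 for
scattered controls are conventionally reported in the tissue-imaging
literature this package serves.

**Protocol.** `hopkins_resampled()` repeats the draw $R$ times — fresh
origins *and* a fresh data subsample each repetition — and averages. The
defaults $m = 40$, $R = 1000$ in a $150 \times 150\,\mu m$ window mirror
the common protocol of analyzing random 40-localization subsets 1000
times per window. Whether such protocols resample origins, subsets, or
both per repetition is usually unstated; resampling both is the
interpretation adopted here, since origins are cheap and the subset is
what the protocol names. Windows with fewer than $m$ points reduce $m$ to
the pattern size with a warning rather than failing, because real
sections vary in density.

Sampling origins are drawn on the *usable* area only: an origin inside an
excluded follicle would measure a distance across forbidden territory and
bias $u$ upward.

**Inference.** `csr_envelope()` simulates the full resampled protocol on
`sims` CSR patterns of matched $n$ and returns the 2.5%/97.5% quantiles
of the null mean-$H$ distribution; an observed mean above the upper
quantile is flagged clustered. Group comparisons of per-window means use
a two-tailed pooled Student's t test (`hopkins_group_summary()`;
`welch = TRUE` switches to the unequal-variance form), reported as
mean ± SD per group in the figure-legend convention.

No edge correction is applied: both $u$ and $w$ are affected comparably
by the window boundary, and the CSR envelope is computed under the exact
same geometry, so the comparison is internally consistent. Note that in
bounded windows mild boundary effects can drag raw means for random data
a little below 0.5 — a reason to judge observations against the
simulated envelope rather than against the nominal constant.

## The proximity test

`proximity_test()` takes target points (HSPC analogs) and reference
points (niche-cell analogs). The observed statistic is the mean
nearest-neighbor distance target → reference. Each of `n_null` (default
999) replicates regenerates the **target** population as CSR with the
same count on the same usable area — density-matched random points —
keeping the references fixed, and recomputes the mean distance. The
one-sided Monte-Carlo p-value uses the +1 correction,

$$ p = \frac{1 + \#\{\bar d_{null} \le \bar d_{obs}\}}{n_{null} + 1}, $$

so $p$ is never exactly zero and is uniform under the null (the test's
type-I rate is verified at ~5% in the acceptance suite). Small $p$ means
the targets are closer to the references than chance placement allows.
The null respects the exclusion mask: HSPCs confined to the red pulp must
be compared against red-pulp-constrained randomness, otherwise forbidden
territory would inflate the null distances.

Distances are exact point-to-point queries by default (`mode =
"point_nn"`, an accelerated sorted-sweep that the test suite verifies
against brute force with zero tolerance). `mode = "raster_dt"` instead
samples a Euclidean distance transform of the rasterized references
(computed with `EBImage::distmap`), for parity with image-processing
pipelines that measure distances on rasters; its quantization error is
bounded by one pixel diagonal, $s\sqrt{2}$, and both modes must and do
agree within that bound. Distances are 2-D (section plane) throughout;
the API is symmetric, so the caller chooses which population is "target".

## The synthetic scene generator

`simulate_scene()` builds windows and populations with known ground
truth:

- **Geometry.** Rectangular windows in micrometres (origin lower-left, y
  upward) with follicles modeled as discs. Real white pulp is irregular,
  but none of the statistics consume follicle *shape* — only point
  coordinates and the exclusion field — so disc geometry suffices for
  calibration. Raster masks (arbitrary shapes) are supported for real
  data via `read_mask()`.
- **CSR fields** (`simulate_csr()`): uniform rejection sampling on the
  usable area, capped at $10^6$ proposals per requested point so fully
  excluded geometry fails loudly instead of spinning.
- **Perifollicular clustering** (`simulate_perifollicular()`): a fraction
  $p$ of points (rounded up) uniform on the annular band within
  `band_width` of the nearest follicle boundary (outside the follicle),
  the rest CSR. Proposals are drawn per-follicle from exact annuli and
  thinned by the number of covering annuli, so overlapping bands are not
  over-weighted. The annulus-mixture is a calibration stand-in: the true
  radial intensity profile of perifollicular accumulation is not known,
  and no claim about it is made.
- **Attraction** (`simulate_attracted()`): a fraction $1 - b$ of targets
  picks a uniform random reference point and displaces it by an isotropic
  Gaussian of scale $\sigma$ (re-drawn until inside the usable area); the
  remaining fraction $b$ is CSR background.
- **Reproducibility.** One integer seed per scene; each population uses a
  sub-stream seed `derive_seed(seed, offset)` =
  `(seed * 48271 + offset * 10007) mod (2^31 - 1)` (niche = 1,
  target = 2), so adding or resizing one population never moves
  another's coordinates. Identical parameters and seed reproduce
  identical coordinates bit-for-bit.

Defaults mirror the tissue protocol the package targets: windows of
$150 \times 150\,\mu m$ with a $40\,\mu m$ follicle, niche populations of
~120 points (plausible segmented cell counts for such windows, within
the commonly processed 40–300 range), $p = 0.8$, `band_width` $10\,\mu m$
(roughly one cell diameter of tight apposition), $\sigma = 5\,\mu m$
(cell-scale attraction), and proximity scenes of 100 references + 50
targets in a $600 \times 600\,\mu m$ field (matching the typical
600-pixel specimen tiles at ~1 μm/px).

**What the generator does not emulate:** irregular white-pulp shapes,
inhomogeneous section-wide density gradients, segmentation noise
(splitting/merging of touching cells), 3-D structure projected into the
section, and between-animal variability. Passing calibration and power
tests on these scenes therefore validates the *statistics*, not any
particular biological imaging pipeline; for real sections the upstream
segmentation quality dominates.

## Coordinate and image conventions

Coordinate tables are comma-delimited with mandatory header `x,y` and
optional `label`, in micrometres unless declared as pixels (then scaled
by `pixel_size` at read time); writing uses 17 significant digits so
write→read is the identity. Label images put pixel (row $i$, column $j$,
0-based) at $x = (j + 0.5)s$, $y = (n_{rows} - i - 0.5)s$ — pixel-center
convention with the image row axis flipped so y grows upward.
`extract_centroids()` labels foreground with 8-connectivity (the common
particle-picking default; declared, not inferred), filters by pixel area
(`min_area` default 1, `max_area` unbounded), keeps border-touching
components, and returns area centroids. Raster masks are used directly
as lookup fields rather than fitted with discs, avoiding shape-fitting
error.

## A worked scene

```{r example}
w <- make_window(150, 150, follicles = list(c(75, 75, 40)))
scene <- simulate_scene(w, n_niche = 120, n_target = 40,
                        clustered_fraction = 0.8, band_width = 10,
                        attraction_scale = 5, seed = 7)

hop <- hopkins_resampled(scene$niche, m = 40, reps = 1000, seed = 11)
env <- csr_envelope(120, w, m = 40, reps = 1000, sims = 50, seed = 12)
hop$mean
c(env$lo, env$hi)
classify_hopkins(hop, env)

prox <- proximity_test(scene$target, scene$niche, n_null = 999, seed = 13)
prox
```

The same chain runs from a YAML config through `run_pipeline()`, which
derives every stage's sub-seed from the config seed, embeds all
per-repetition values in its JSON report (so every reported mean is
recomputable from the report alone), and is byte-identical across reruns.

## Numerical choices and problem sizes

- Usable areas are computed by integrating the excluded cross-section of
  the disc *union* on a 50k-point grid (overlapping follicles are not
  double-subtracted), cross-checked against Monte-Carlo integration in
  the tests.
- Nearest-neighbor ties need no breaking: only distances enter the
  statistics, never neighbor identities. Duplicate coordinates are legal
  (two cells can share a centroid at pixel resolution) and give
  zero-distance neighbors, handled exactly.
- Monte-Carlo p-values use the +1 correction; envelopes use type-7
  quantiles of the simulated null means.
- The test and calibration suites run the full protocol ($R = 1000$) for
  the headline checks — 20 CSR windows for the 0.5 calibration, a
  200-simulation envelope with 100 clustered and 100 CSR scenes for
  direction and coverage, 100 attraction scenes plus 200 null scenes for
  proximity power and type-I — and reduced repetition counts
  ($R = 150$–300) for auxiliary property checks, sizes chosen to keep
  the statistical resolution of each assertion well above its tolerance.

## Limitations

- 2-D only; no volumetric distance transforms or 3-D scenes.
- Centroid-to-centroid distances; no surface-to-surface or shape-aware
  proximity.
- No other clustering statistics (Ripley's K, pair correlation,
  Clark–Evans) — natural extensions, deliberately out of scope.
- No fluorescence preprocessing: inputs are assumed already segmented or
  binarized.
- The inferential unit (windows within animal vs animals) is left to the
  caller: reports expose per-window records so either aggregation can be
  computed.
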