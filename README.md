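# nichespat

Spatial point-pattern statistics for tissue niche localization in 2-D
sections.

During extramedullary hematopoiesis, splenic mesenchymal niche cells
redistribute from a scattered arrangement in the red pulp to the
perifollicular band around the white pulp, and hematopoietic
stem/progenitor cells (HSPCs) localize next to them. Given segmented cell
coordinates (in micrometres) from such sections, `nichespat` answers the
two statistical questions this raises:

- **Do the cells cluster?** A subsampled **Hopkins clustering-tendency
  statistic** with a complete-spatial-randomness (CSR) Monte-Carlo
  envelope. For `m` random sampling origins with nearest-data distances
  `u_i` and an `m`-point data subsample with nearest-other-point
  distances `w_i`,

  `H = Σ u_i^k / (Σ u_i^k + Σ w_i^k)`,  `k = 1` (plain, default) or
  `k = 2` (powered),

  repeated `R` times per window (defaults `m = 40`, `R = 1000` in a
  150 × 150 μm window). CSR gives `H ≈ 0.5`; clustering gives `H > 0.5`.
  Windows may carry circular or raster exclusion regions (white pulp),
  which constrain both the sampling origins and every null simulation.

- **Are targets near references?** A **nearest-neighbor proximity test**:
  the observed mean target→reference NN distance is compared against
  replicates in which the target population is regenerated as
  density-matched random points on the same usable area, with
  Monte-Carlo p-value `(1 + #{null ≤ obs}) / (n_null + 1)`.

A synthetic tissue-scene generator (disc follicles, perifollicular
annulus mixtures, Gaussian attraction between populations, fully
seed-reproducible) provides ground truth for calibration and power
analysis. I/O covers coordinate CSV tables, centroid extraction from
binary label images (8-connected components with area filters), and
exclusion masks as circle files or rasters. Intended users: imaging labs
quantifying stromal-niche organization, and anyone needing a calibrated
clustering/proximity readout for 2-D point data in bounded, partially
masked windows.

## Worked example

```r
library(nichespat)

# a 150x150 um window with a 40 um follicle; a niche population with 80%
# of cells in a 10 um perifollicular band; 40 HSPC-like targets attracted
# to the niche with 5 um displacement scale
w <- make_window(150, 150, follicles = list(c(75, 75, 40)))
scene <- simulate_scene(w, n_niche = 120, n_target = 40,
                        clustered_fraction = 0.8, band_width = 10,
                        attraction_scale = 5, seed = 7)

hop <- hopkins_resampled(scene$niche, m = 40, reps = 1000, seed = 11)
hop
#> Hopkins analysis (m = 40, R = 1000, plain variant)
#>   mean H = 0.7483 (SD of repetitions 0.0347)
#>   H > 0.5: clustered; H ~ 0.5: random; H < 0.5: regular

env <- csr_envelope(120, w, m = 40, reps = 1000, sims = 50, seed = 12)
env
#> CSR envelope for mean Hopkins (n = 120, m = 40, R = 1000, 50 sims)
#>   [2.5%, 97.5%] envelope: [0.4615, 0.5394]
classify_hopkins(hop, env)
#> [1] "clustered"

prox <- proximity_test(scene$target, scene$niche, n_null = 999, seed = 13)
prox
#> proximity test (point_nn mode, 999 null replicates)
#>   observed mean NN distance: 3.46 +/- 2.24 um (n = 40)
#>   density-matched random:    12.15 +/- 1.56 um
#>   Monte-Carlo p = 0.001 (small = closer than chance)
```

Reading: the niche population's mean Hopkins index (0.75) lies far above
the CSR envelope for 120 points in this window ([0.46, 0.54]), so its
perifollicular accumulation is detected as clustering; the targets sit on
average 3.5 μm from the nearest niche cell where density-matched random
points would sit 12.2 μm away, and no null replicate came as close
(p = 0.001, the minimum attainable with 999 replicates).

For real data, replace the simulated patterns with
`read_points("venus.csv")` / `read_points("hspc.csv")`, a mask from
`read_mask()`, and use `tile_windows()` to split large sections into
150 × 150 μm windows with at least `m` points. `run_pipeline()` drives
the whole chain from a YAML config and writes a self-contained,
rerun-stable JSON report.

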