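# nanopaint

Quantitative analysis of **protein-PAINT** single-molecule localisation
data, with a built-in synthetic data generator for end-to-end validation.

In PAINT imaging a diffusing probe (e.g. a recombinant tandem-SH2 or SH3
domain) binds its molecular target transiently, so one target produces a
spatially confined cluster of repeated binding events. Two things follow:
the **kinetics** of those events identify and count the underlying binding
sites, and the refined site positions support **nanoscale spatial
statistics** of how signalling molecules are organised — for example,
whether phosphorylated receptors and adaptors inside membrane signalling
condensates are randomly mixed, aggregated, or regularly spaced and
interleaved. nanopaint is aimed at researchers analysing such data
(localisation tables from an upstream spot-fitting tool) and at method
development, where every stage can be exercised against simulated ground
truth.

## What it computes

| Stage | Model / statistic |
|---|---|
| `link_events()` | localisations → binding events: chaining within 80 nm, bridging up to 5 dark frames |
| `detect_sites()`, `assign_events()` | event density maps (5 nm px) → local maxima → 2-D Gaussian centroids; events assigned within 45 nm |
| `fit_koff()`, `fit_kon()`, `site_kinetics()` | censored exponential (or 2-component mixture) MLE for k_off; left-truncated exponential MLE on dark gaps, k_on = dark rate / [probe] (µM⁻¹s⁻¹); a site of valence m has aggregate on-rate m·k_on·c |
| `segment_condensates()`, `condensate_stats()` | Otsu segmentation of diffuse low-affinity binding density (10 nm px, σ = 1 px, ≥ 0.01 µm²), inside/outside classification, per-condensate densities, influx rates, count–area regressions |
| `pair_correlation()` | FFT auto/cross-correlation g(r), mask-edge normalised, radially averaged (CSR → 1) |
| `ripley_l()`, `ripley_l_masked()`, `cross_ripley()` | K(r) = A/(n(n−1)) Σ w⁻¹ 1(d ≤ r) with isotropic raster-mask edge weights; reported as L(r) − r = √(K/π) − r; per-condensate normalisation pooled across regions |
| `nn_cdf()`, `dbscan_clusters()` | nearest-neighbour distance CDFs; DBSCAN (ε = 200 nm, 3 points) |
| `sim_config()`, `simulate_paint()` | CSR / hard-core / jittered-lattice / condensate-field / interleaved point processes with exponential on–off traces and a frame-wise rendering model |

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and result types have `autoplot()` methods. `run_pipeline()`
chains the stages and writes tables, masks and a checksummed manifest.

## Worked example

Simulate a field of isolated decavalent-receptor-like sites (aggregate
k_on = 10 µM⁻¹s⁻¹ at 10 nM probe, k_off = 2 s⁻¹, 50 ms frames, 10 nm
precision), then run the analysis blind to the truth:

```r
library(nanopaint)

mv  <- movie_params(exposure_s = 0.05, n_frames = 6000, probe_conc_uM = 0.01)
sim <- sim_config(sim_window(4000), "hardcore", density_um2 = 3,
                  hardcore_nm = 200, k_on = 10, k_off = 2,
                  movie = mv, precision_nm = 10, seed = 42)
res    <- simulate_paint(sim)
events <- link_events(res$locs, link_radius_nm = 80, max_gap_frames = 5,
                      exposure_s = 0.05, n_frames = 6000)
sites  <- detect_sites(render_density(events, 5, sim$window), precision_nm = 10)
asg    <- assign_events(sites, events, assign_radius_nm = 45)
kin    <- kinetics_table(asg, mv)
```

This prints (11,053 localisations → 1,017 events → 39 accepted sites, the
same count the generator placed):

```
   site n_events  k_on k_off mean_bound_time_s
1     1       36  13.3  1.77             0.590
2     2       33  13.0  1.68             0.620
3     3       32  12.3  2.26             0.467
...
median k_on: 9.8      # generating value 10 uM^-1 s^-1
median k_off: 1.93    # generating value 2 s^-1
```

Each row is one binding site: `n_events` rebinding events were assigned to
it, its dark gaps give `k_on` (per-site medians scatter around the
generating rate; the 95% CI columns not shown here quantify that), and its
bound times give `k_off`. `autoplot(ripley_l_masked(...))` or
`autoplot(pair_correlation(...))` display the spatial profiles with their
pooled confidence bands.

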