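---
title: "Models and methods behind nanopaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanopaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nanopaint analyses protein-PAINT single-molecule localisation data. In PAINT
imaging a freely diffusing probe binds its molecular target transiently, so
each target produces a cluster of repeated, spatially confined binding
events; the kinetics of those events carry information about the number and
identity of the underlying binding sites, and the refined site positions
support nanoscale spatial statistics. This vignette describes the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The measurement model and its inverse

The pipeline inverts a simple forward model, which the simulator
(`simulate_paint()`) also implements:

1. **Sites.** Binding sites sit at fixed positions. A site with valence
   $m$ (e.g. an immunoreceptor with $m$ phosphorylated ITAMs within one
   diffraction-unresolvable spot) is modelled as a single-occupancy
   alternating renewal process: dark intervals are
   $\mathrm{Exp}(m\,k_{on}c)$ with the probe concentration $c$ in µM and
   $k_{on}$ in µM⁻¹s⁻¹, bound intervals are $\mathrm{Exp}(k_{off})$,
   optionally a two-component mixture. Simultaneous double occupancy is not
   modelled; avidity effects appear only through the mixture option.
2. **Localisations.** A bound interval contributes one localisation to every
   frame whose exposure it covers for more than half of the frame, at the
   site position plus isotropic Gaussian noise with SD equal to the
   localisation precision (default 10 nm; 10–15 nm is the typical working
   range). The half-frame rule is symmetric, so the rendered duration equals
   the true duration in expectation, and an event must exceed half an
   exposure to be seen at all.
3. **Diffuse field.** Low-affinity, non-rebinding probe binding inside
   condensates (the segmentation channel) is a spatio-temporal Poisson
   process on the domain mask, each event one frame long at a fresh
   position.

The analysis then proceeds in the reverse direction:

* `link_events()` chains localisations within 80 nm across consecutive
  frames, bridging up to 5 dark frames; a 6th splits the event. Bridged
  dark frames count toward the event duration, and the event position is
  the precision-weighted mean of its localisations. Ambiguous continuations
  join the nearest open chain; ties break towards the chain with the lower
  start frame (the upstream tool this step mirrors does not specify a rule,
  so we state ours).
* `detect_sites()` renders binding-event maps at 5 nm pixels, smooths with
  a Gaussian of SD equal to the precision, takes local maxima with
  non-maximum suppression over $2\times$ precision, and refines each
  candidate with an elliptical 2-D Gaussian fit over a $\pm 3\times$
  precision window. Acceptance requires at least `min_events` (default 5)
  events within three precisions of the centroid and fitted widths in
  $[\text{precision}/3,\ 2\times\text{precision}]$. The acceptance
  amplitude is the raw event count near the centroid rather than the fitted
  Gaussian volume: events built from many localisations scatter less than
  single-localisation events, so the fitted core can underestimate the
  event count of a genuine site. The width band's lower edge also bounds
  the optimiser, because the 5 nm raster cannot resolve narrower widths.
* `assign_events()` assigns each event to the nearest accepted centroid
  within 45 nm (≈ three precisions). Sites whose assignment discs
  intersect (centroids closer than 90 nm) are flagged `overlapping`; their
  apparent on-rates are inflated by event sharing and downstream analyses
  can filter on the flag.

## Kinetic inference

`fit_koff()` is a censored exponential MLE: events touching a movie
boundary enter as survival terms. Durations are whole frames, so the
likelihood uses `duration − exposure/2`; because detection requires
covering more than half a frame and the exponential is memoryless, the
measured duration overshoots the conditional mean by half a frame, and the
offset removes that bias to first order. The two-component model is fitted
by direct likelihood maximisation over (log rates, logit fraction), with
BIC selection under `model = "auto"`.

`fit_kon()` estimates the aggregate dark rate from inter-event gaps and
divides by the probe concentration. Gaps of up to `max_gap + 1` frames are
invisible — the linker bridges them — so the likelihood is left-truncated
at $(\text{max\_gap}+1)\times\text{exposure}$ and the MLE is
$n / \sum(g_i - t_0)$. Without the truncation the rate is biased downward,
noticeably at high rates. A least-squares fit of the empirical gap CDF to
$1 - e^{-\lambda (t - t_0)}$ is available as `method = "cdf"` for parity
with cumulative-distribution fitting; the two agree within a few percent on
clean samples. Gaps cut by the movie boundaries are never formed (only
inter-event gaps are used), and a site with a single event yields a
dissociation estimate with the association side flagged undefined.

Two caveats the estimators do not correct: events shorter than half a frame
are undetected, which thins the event sequence and lowers the apparent
dark rate by the miss fraction $1 - e^{-k_{off}\,\text{exposure}/2}$
(≈ 2–12 % in the regimes here) — this cancels in valence ratios; and
bridged short gaps merge events, lengthening apparent bound times by a few
percent when $k_{off}$ and the dark rate are both fast.

## Condensate segmentation

`segment_condensates()` renders the diffuse-field events at 10 nm pixels,
smooths with σ = 1 pixel, thresholds with Otsu's method computed per cell
from the smoothed image (the threshold should match the image it
binarises), removes regions under 0.01 µm², fills holes and labels. A cell
footprint (`cell_mask()`) is Otsu on a 50 nm render smoothed at σ = 10
pixels, largest component, holes filled; user-supplied masks can stand in.
Relative radial positions (0 = cell edge, 1 = centre) follow the ray from
the cell centroid through the condensate centroid to the mask boundary.
Otsu on the smoothed edge ramp erodes domains by roughly a pixel, so
recovered areas run a few percent small for ~300 nm domains; site
densities inherit a comparable, partially cancelling bias because edge
sites fall off the mask together with the edge area.

## Spatial statistics

**Pair correlation.** Species are binned at 10 nm, correlated by
zero-padded FFT, divided by the FFT autocorrelation of the window mask
(finite-window edge normalisation), normalised by the species densities,
and radially averaged in one-pixel bins; complete spatial randomness gives
$g(r) = 1$. For autocorrelation the self-pair term is removed from the
zero-lag bin and the reported $r = 0$ value is pinned to 1 as the
zero-shift reference — that bin is not interpretable and peak searches
skip it (`profile_peak()` starts at the first non-zero bin and requires a
clustering peak to exceed 1). Cross-correlation has no self term, so its
zero bin is the computed value.

**Ripley's K/L.** $K(r) = \frac{A}{n(n-1)}\sum_{i \ne j} w_{ij}^{-1}
\mathbf{1}(d_{ij} \le r)$ with isotropic edge weights: $w_{ij}$ is the
fraction of the circle of radius $d_{ij}$ centred on point $i$ that lies
inside the window, evaluated on arbitrary raster masks by sampling 72
equally spaced circle points, floored at 0.1 to bound the variance of
$w^{-1}$. The profile is reported as the variance-stabilised
$L(r) - r = \sqrt{K(r)/\pi} - r$. The implementation equals a naive
double-loop evaluation of the same formula to $10^{-9}$ (tested), so the
vectorisation is purely mechanical. Mask-restricted variants
(`ripley_l_masked()`, `cross_ripley_masked()`) evaluate each condensate
with its own raster, count and area — this removes the dominant
condensate-scale (primary) clustering so that nanoscale (secondary)
structure such as hard-core dispersion becomes visible — and pool curves
as the unweighted mean over regions with at least 5 points, with
1.96 × SEM as dispersion. Default grids are 5 nm steps to 300 nm within
condensates and 10 nm steps to 1 µm for whole-cell analyses; grids beyond
half the window extent are truncated with a warning.

For the cross function we report $L_{AB}(r) - r$ against the independence
null; "normalisation to independent processes with matched densities" could
also be read as subtracting a simulated null, which is available by running
`cross_ripley` on permuted species labels, but the closed form is the
default. Note a structural property of the cumulative $L$: for a species
arranged in a radial shell of finite width around another, the maximum of
$L_{AB}(r) - r$ falls at the shell's outer edge (about the shell radius
plus twice its width SD), not at its centre.

**Nearest neighbours and DBSCAN.** `nn_cdf()` returns empirical CDFs of
nearest-neighbour distances (self excluded for homotypic pairs); no edge
correction is applied, which depresses the CDF slightly near the window
border. `dbscan_clusters()` is the standard algorithm at ε = 200 nm and 3
points minimum (the point itself counts), with convex-hull areas as the
cluster extent.

## The synthetic generator as a validation instrument

`sim_config()` fixes the study conditions: 50 ms exposure, probe
concentrations 0.001–0.01 µM, precision 10 nm, and spatial processes
chosen to emulate the features the analysis must resolve — complete
spatial randomness; dart-throwing hard core (approximate Matérn II with a
retry cap and an up-front triangular-packing bound check); jittered
triangular lattices for regular spacing; disc condensate domains
(optionally with a uniform radius range) carrying hard-core sites at 80
µm⁻² (dense, pLAT-like) or 20 µm⁻² (sparse, pTCR-like); and a two-species
interleaved mode placing ~4 B sites per A site in a tight radial shell
(SD 5 nm) at 100 nm with a 15 nm mutual exclusion. The shell is kept
narrow deliberately: it represents a characteristic cross-species distance,
and a broad shell would displace the cumulative cross-L maximum from the
radius it is meant to encode. Scale-recovery experiments for both
dispersion scales (40 and 25 nm) run at the dense 80 µm⁻² so that pair
statistics just above the inhibition distance are populated; at 20 µm⁻²
fewer than one pair per condensate falls near 25 nm and the pooled argmin
is noise-dominated. Regularity and hard-core placement are validation
stand-ins for the observed spacing statistics, not mechanistic claims
about how such patterns arise in cells.

Not emulated: photophysics (blinking, bleaching), background fluorophores,
drift, camera noise, irregular condensate shapes, and mechanistic
multivalent rebinding. Passing recovery tests therefore demonstrates that
the estimators invert this forward model at realistic densities, noise and
sampling — not that real data are free of those additional effects.

## Problem sizes and reproducibility

Validation runs use desk-scale fields: ~50 condensate domains of radius
300 nm in a 12–13 µm window, 4000 frames (200 s) at ~20 events per site,
and 2000–4000 gaps for kinetic fits. One master seed drives every stage
through deterministically derived sub-streams, so identical configurations
reproduce outputs bit-identically; `run_pipeline()` records the
configuration and per-file MD5 checksums in a manifest. Known limitations
worth restating: segmentation area bias of a few percent at 300 nm domain
scale, the detection-miss thinning of absolute on-rates, no HDF5 reader
(localisation tables exchange as nm CSV or camera-pixel CSV with a YAML
sidecar), and edge-uncorrected nearest-neighbour CDFs.
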