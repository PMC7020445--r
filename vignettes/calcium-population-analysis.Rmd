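---
title: "Subpopulation analysis of calcium imaging in mixed retinal cultures"
author: "CalciPop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subpopulation analysis of calcium imaging in mixed retinal cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CalciPop)
```

## The analysis

CalciPop implements an end-to-end analysis of time-lapse Fluo-4 calcium
imaging of heterogeneous (mixed neuronal/glial) cultures, of the kind used to
compare an unstressed culture with one exposed to a CoCl2 hypoxia mimetic:

1. **Segmentation** of active cells from the movie by principal-component
   analysis of pixel time series (`segmentMoviePCA`), and extraction of
   per-cell mean-intensity traces (`extractTraces`).
2. **Trace processing**: second-order polynomial photobleaching correction
   (`correctBleach`), deltaF/F0 normalisation against a per-cell basal level
   (`computeDff`, `normalizeTraces`), and calcium spike detection
   (`detectSpikes`).
3. **Population analysis**: k-means clustering (k = 4) of the two features
   (spike count per 600 s, Ca2+max = maximum deltaF/F0) on the control
   condition (`clusterFeatures`), naming of clusters as
   hyperactive / moderate / low / silent (`nameClusters`), derivation of
   axis-aligned class boundaries from the control clusters
   (`deriveBoundaries`), boundary classification of all conditions
   (`classifyCells`), subsampled subpopulation profiling
   (`subsampleProfiles`) and Kruskal-Wallis condition comparisons
   (`compareConditions`).
4. **Companion assays**: 2^-ddCt qPCR fold changes (`foldChangeDDCt`),
   blank-subtracted percentage viability (`viabilityPercent`), Jarque-Bera
   normality and 10-90% whisker box summaries.

Every stage is exercised against a ground-truthed synthetic generator
(`simulatePopulation`, `simulateMovie`, `simulateQpcr`,
`simulateViability`), which is itself first-class, tested code.

## The signal model

A cell's raw fluorescence is modelled as

    F(t) = F0 * (1 + dff(t)) * (1 + b t + c t^2) + e(t),  e ~ N(0, sigma^2)

where `dff(t)` is the calcium activity (a sum of event kernels with a
one-frame rise and exponential decay, tau = 15 s), the quadratic factor is
multiplicative photobleaching, and `e` is additive imaging noise. The
recording is 60 frames at 10 s (600 s).

Bleach correction fits `a + b t + c t^2` by least squares and divides it out
anchored at the first frame: `corrected(t) = F(t) * trend(0) / trend(t)`.
Division, rather than subtraction, matches the multiplicative nature of
fluorophore loss and makes the whole chain invariant to detector gain: any
rescaling of the raw traces leaves deltaF/F0, spike trains and features
unchanged (asserted to 1e-10 in the tests). A trend fitted through zero
triggers a subtractive fallback with a warning. Because the generator's
bleaching has exactly the fitted functional form, the correction stage is
exactly identifiable; the residual coefficient of variation on spike-free
bleached cells measures the correction itself, and the tests require it to be
below 1% for bleaching up to 30% total decay. Note that divisive correction
necessarily amplifies late-frame noise by `1/trend(t)` (up to about 1.25x at
20% bleach) — this is a property of bleaching, not of the detector.

F0 is the 20th-percentile of the corrected trace: a low quantile is robust to
spikes so long as they occupy a minority of frames. Two consequences are
worth knowing. For heavily spiking cells the quantile sits above the true
baseline, slightly compressing deltaF/F0; and for a pure-noise trace the
20th percentile sits 0.84 noise-sd *below* the mean, so baseline deltaF/F0
is centred slightly above zero — which effectively lowers any absolute
detection threshold by roughly 0.85 sigma.

## Spike detection thresholds

Spikes are local maxima subject to three thresholds: minimum amplitude
(`ampMin`, default 0.25 deltaF/F0), minimum topographic prominence
(`prominenceMin`, default 0.2) and minimum separation (2 frames, larger peak
wins). The defaults are chosen so that the amplitude threshold sits about
four standard deviations above the baseline at a deltaF/F0 noise level of
0.05 (a realistic upper bound for this kind of recording): with ~57
interior frames per trace, a three-sigma threshold already admits spurious
noise peaks in several percent of cells per recording, while at four sigma
the expected false-positive rate drops below one percent. All thresholds are
plain configuration and are recorded on the spike table the detector
returns. An optional spike-masked refit of the bleach trend
(`normalizeTraces(maskSpikes = TRUE)`) removes the small upward bias that
spikes impose on the fitted quadratic; at the sparse spiking the defaults
emulate the bias is small and the option is off by default.

## Activity classes and boundaries

The four classes follow the standard boundary rules for this assay: more
than 6 spikes per 10 min is hyperactive; otherwise Ca2+max above 0.5 with at
least one spike is moderate; otherwise zero spikes is silent and the rest is
low activity. `classifyCell` is a total function on finite non-negative
features. The low/silent split at zero spikes is a design choice — the two
lower-activity groups are distinguished visually in this assay but no
published rule exists. Likewise the hyperactive rule uses spike count alone,
reading the published boundaries literally.

k-means is fitted on min-max scaled features (counts and amplitudes differ
in scale by roughly an order of magnitude; unscaled Euclidean k-means would
be count-dominated), with k-means++ seeding and 50 restarts keeping the best
within-cluster sum of squares, deterministic given the seed. Boundaries
derived from a named control clustering are midpoints between adjacent
classes' extreme cells, with fallbacks to the published defaults (6 spikes,
0.5 deltaF/F0) when a class is missing.

Subpopulation profiles draw 90 cells (the published sample size, which takes
precedence over the also-published "60% of 160" = 96) without replacement,
five times, classify each draw and report percentages; percentages always
sum to 100. Condition comparisons run a Kruskal-Wallis test per class on the
per-repeat percentages at alpha = 0.05, treating subsample repeats as the
replication unit (the underlying grouping unit is not published; see
Limitations).

## Segmentation details

The movie (frames x pixels) is centred per pixel over time; the leading
temporal eigenvectors are obtained from the frame-by-frame covariance (an
economical route when frames << pixels), and the activity image is the
root-sum-of-squares of the top-component pixel loadings — the temporal
standard deviation each pixel exhibits inside the retained subspace. At most
10 components are kept, capped at 99% explained variance.

Because active cells occupy a small minority of pixels, the activity
histogram is overwhelmingly background; a global Otsu threshold then tends
to land above dim cells. The default threshold is therefore the robust
background estimate `median + 6 * MAD` of the activity image; Otsu (applied
to the log-activity image) and a plain quantile cut are available
alternatives. Connected components use 8-connectivity and are size-filtered
to [20, 2000] pixels. Thresholding operates on relative statistics of the
activity image, so segmentation is equivariant to intensity scaling. A
variance-based segmentation (`segmentMovieVariance`) is provided behind the
same interface as a fallback. Coordinates are (row, col); frame times are
`(frame - 1) * frameInterval` seconds.

## What the generator emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes: a
mixed population of four activity classes sampled at 10 s for 600 s,
Poisson-timed transients with fast rise and exponential decay, multiplicative
quadratic bleaching, additive Gaussian noise, and disc-shaped spatially
disjoint footprints. Defaults: control composition 10/30/40/20%
(hyperactive/moderate/low/silent), hypoxia 25/40/25/10% with hyperactive
amplitude raised from 0.9 to 1.2 — qualitative mimics of the direction of
the published shifts; no per-class prevalences or amplitude statistics are
published, so the presets are configuration, not estimates.

Three generator design choices matter for interpretation:

* **Exact composition.** Class proportions are apportioned to integer counts
  (largest remainder), not drawn multinomially, so same-configuration
  populations share one true composition. This is what makes
  "identical donors" identical: with multinomial composition, between-donor
  composition noise alone would dominate the subsampling variance and no
  robustness comparison could hold.
* **Boundary-consistent counts.** Spike counts are Poisson rejection-sampled
  into each class's admissible range (>= 7, 1-6, 1-6, 0) by default, so the
  generating label of a cell is in principle recoverable from its features.
  `enforceCountRange = FALSE` gives plain Poisson counts (used when testing
  the Poisson sampling itself).
* **Detectable low-activity events.** The low-class amplitude
  (0.35 +- 0.04) is placed at least ~3.5 sigma above the detection floor and,
  including the worst-case stacking of two events two frames apart
  (factor 1.26), below the 0.5 Ca2+max boundary. Cells whose overlapping
  events genuinely push deltaF/F0 past 0.5 are classified moderate by the
  boundary rules whatever their generating label; at the default event rates
  this affects about 1% of cells and is irreducible without changing the
  class definitions themselves.

What the generator does *not* model: biophysical calcium buffering and
indicator kinetics, motion, overlapping or irregular cell footprints,
correlated (network) activity across cells, non-Gaussian or
intensity-dependent (shot) noise, focus drift, and any gene-expression or
cell-death dynamics. Passing tests therefore demonstrate correctness of the
computations under the stated signal model, not performance on real
microscope data — in particular real segmentation must cope with touching
cells and real spike detection with correlated noise, both out of scope
here.

## Verification problem sizes

The test-suite properties run at the following sizes, chosen to exercise the
study-scale regime while keeping the suite quick: gain invariance on a
160-cell population; bleach recovery on 200 spike-free cells spanning 8-30%
decay; spike-count recovery on 500 cells with event amplitudes >= 0.5 and
deltaF/F0 noise 0.05 (bleach disabled there: the detector is measured in
isolation, bleach robustness has its own paired-simulation check); a 256 x
256, 60-frame, 50-cell movie at 5% noise for segmentation; 160-cell
populations for clustering, boundary transfer and the control-vs-hypoxia
contrast; twenty 4-donor replications for the donor-robustness null;
a 1e5-draw permutation oracle for Kruskal-Wallis; 100-seed averages for the
noisy ddCt round trip.

## Known limitations

* With subsample repeats as the replication unit, the five 90-of-160 draws
  from one population are not independent experiments; any cell-level
  classification noise acts as a shared donor-level offset and makes the
  Kruskal-Wallis donor comparison slightly anti-conservative. With identical
  synthetic donors the per-class non-rejection rate sits near, not above,
  its nominal 95% — a short 20-replication series can dip below 90% for a
  class by chance.
* The quantile baseline compresses deltaF/F0 for cells active in a majority
  of frames (hyperactive cells at high rates); Ca2+max comparisons across
  classes inherit a small downward bias there.
* Quadratic bleach correction leaves a residual when the true trend is not
  quadratic (e.g. a product of linear and quadratic factors contains a cubic
  term); the residual floor is a fraction of a percent of baseline.
* The k-means step fixes k = 4; no model selection over k is attempted, and
  no attribution of spiking signatures to cell types (neuron vs glia) is
  made.
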