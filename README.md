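# CalciPop

Subpopulation analysis of time-lapse calcium imaging in mixed retinal
cultures.

## The problem

Primary mixed retinal cultures (neurons, astrocytes, Müller glia, microglia)
show highly heterogeneous spontaneous Ca²⁺ activity. Under a CoCl₂-mimicked
hypoxic insult the composition of that activity shifts: more hyperactive and
moderately active cells, fewer low-activity cells. Quantifying such a shift
requires a pipeline that goes from a Fluo-4 fluorescence movie to per-cell
activity features to subpopulation percentages, with honest statistics at
each step. CalciPop provides that pipeline for R, aimed at cell biologists
and imaging labs analysing 10 s / 600 s time-lapse recordings, together with
the companion qPCR (2^−ΔΔCt) and Alamar-blue viability computations such a
study uses.

## The method

For each segmented cell with raw fluorescence F(t):

* **Bleach correction** — fit F ≈ a + b·t + c·t² by least squares and divide
  the trend out, anchored at t = 0: corrected(t) = F(t)·trend(0)/trend(t).
* **Normalisation** — ΔF/F0 = (F − F0)/F0 with F0 the 20th percentile of the
  corrected trace.
* **Spike detection** — local maxima with ΔF/F0 ≥ 0.25, topographic
  prominence ≥ 0.2 and ≥ 2 frames separation (all configurable; values are
  logged with the output).
* **Features** — spike count per 600 s and Ca²⁺max = max ΔF/F0.
* **Clustering** — k-means (k = 4, k-means++ seeding, 50 restarts) on
  min–max scaled features of the control condition; clusters are named
  hyperactive / moderate / low / silent via the boundary rules
  (> 6 spikes/10 min ⇒ hyperactive; Ca²⁺max > 0.5 with ≥ 1 spike ⇒ moderate;
  0 spikes ⇒ silent; else low) and boundaries re-derived from the control
  clusters classify the treated condition.
* **Profiling** — 90 cells drawn without replacement from each 160-cell
  population, 5 times; class percentages per draw; Kruskal–Wallis per class
  across conditions at α = 0.05.

Segmentation of movies uses principal-component analysis of pixel time
series: an activity image is built from the top temporal components,
thresholded robustly (median + 6·MAD), and split into 8-connected,
size-filtered components. qPCR fold changes use
2^−ΔΔCt with ΔCt = Ct(target) − Ct(reference) per replicate; viability is
100·(A − Ā_blank)/(Ā_control − Ā_blank).

A ground-truthed synthetic generator (`simulatePopulation`, `simulateMovie`,
`simulateQpcr`, `simulateViability`) emulates the assumed signal structure —
four activity classes, Poisson-timed transients with exponential decay
(τ = 15 s), multiplicative quadratic bleaching, Gaussian noise, disjoint
disc footprints — so every stage is testable without external data. See the
methods vignette (`vignettes/calcium-population-analysis.Rmd`) for the model,
parameter choices and limitations.

## Worked example

```r
library(CalciPop)

ctl <- simulatePopulation(conditionPreset("control"), seed = 1, condition = "control")
hyp <- simulatePopulation(conditionPreset("hypoxia"), seed = 2, condition = "hypoxia")
ctl
#> CaSimulation (control): 160 cells, 60 frames
#> hyperactive    moderate         low      silent
#>          16          48          64          32

ftC <- computeFeatures(normalizeTraces(simTraces(ctl)))
ftH <- computeFeatures(normalizeTraces(simTraces(hyp)))
model <- clusterFeatures(ftC, k = 4, seed = 1)
model
#> ClusterModel: k = 4, 160 cells, tot.withinss = 1.6199
#>   spike_count ca_max
#> 1       0.000  0.078
#> 2       2.891  0.778
#> 3      10.059  1.098
#> 4       2.375  0.385

mapping <- nameClusters(model)        # silent / moderate / hyperactive / low
bounds  <- deriveBoundaries(model, mapping, ftC)
#> deriveBoundaries: spikeThr = 6.000, ampThr = 0.594

profiles <- rbind(subsampleProfiles(ftC, bounds, seed = 11),
                  subsampleProfiles(ftH, bounds, seed = 12))
aggregate(profiles[activityClasses()], list(condition = profiles$condition), mean)
#>   condition hyperactive moderate low silent
#> 1   control        11.1     31.6  38   19.3
#> 2   hypoxia        24.7     39.3  26   10.0

compareConditions(profiles)
#>         class        H           p significant
#> 1 hyperactive 6.987578 0.008207736        TRUE
#> 2    moderate 4.840244 0.027802962        TRUE
#> 3         low 6.859756 0.008815858        TRUE
#> 4      silent 6.987578 0.008207736        TRUE
```

The four k-means centroids land on the four activity classes; classifying
the hypoxia population with control-derived boundaries shows the hyperactive
fraction rising from ~11% to ~25% and the low-activity fraction falling from
38% to 26%, each shift significant by Kruskal–Wallis — the directional
signature of the hypoxia preset.

An end-to-end run (segmentation or simulation through figures, with a
manifest of every output) is available as
`runPipeline(pipelineConfig(...))`, and a thin command-line wrapper lives at
`inst/scripts/calcipop`.

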