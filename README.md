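# felidniche

Spatio-temporal niche partitioning analysis for camera-trap surveys of
sympatric carnivore guilds — motivated by the five Bornean felids (Sunda
clouded leopard, bay cat, marbled cat, leopard cat, flat-headed cat), but
species-agnostic. Ecologists studying coexistence want to know *where* a
guild's members occur, *when* they are active, and *with whom* they co-occur.
`felidniche` implements all three arms from raw camera-trap records:

* **Habitat** — multi-scale logistic occurrence models. Each covariate is
  aggregated by circular focal-window means at radii of 120–7680 m; the
  best-supported scale per covariate is the lowest-AIC univariate fit;
  variables are screened at p ≤ 0.2, pruned at |Pearson r| > 0.7 (keeping
  the lower-AIC member), and the survivors enter an all-subsets logistic
  ensemble with intercept and trap-effort forced. Models are combined by
  Akaike weights w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2) into full-average
  coefficients β̄ = Σ w_i β_i (zero for absent terms), unconditional SEs
  √(Σ w_i [SE_i² + (β_i − β̄)²]), and importances Σ w_i over models
  containing a term; occurrence maps follow p = e^z/(1 + e^z).
* **Time** — diel activity as circular kernel densities with von Mises
  kernels and the plug-in bandwidth
  κ* = [3 n κ̂² I₂(2κ̂) / (4√π I₀(κ̂)²)]^{2/5}; pairwise overlap by the
  coefficient of overlapping Δ ∈ [0, 1] (Δ₁ on a grid when the smaller
  sample has < 75 records, Δ₄ from density ratios at the observed points
  otherwise), with bias-adjusted percentile intervals from a smoothed
  bootstrap and a percentile classification (5th/10th/90th/95th) of each
  felid's overlap profile across candidate species.
* **Prey** — felid occurrence modelled from raw candidate-prey detection
  counts (≥ 20 independent detections to qualify) through the same
  all-subsets averaging machinery.

A synthetic landscape/community generator with known parameters backs every
stage, so the whole pipeline is testable without any field data. Rasters are
plain-text ESRI ASCII grids handled by a lightweight in-memory raster class.

## Worked example

Simulate a survey of 578 stations in 10 clustered survey areas (mean effort
125 trap-nights), with occurrence driven by tree cover at a true scale of
960 m (β = +1.0) and human footprint at 3840 m (β = −0.7), plus an unrelated
"scrub" layer:

```r
library(felidniche)

cfg <- synthetic_config(
  covariates = list(
    list(name = "tree_cover",      kind = "continuous", range = 240),
    list(name = "human_footprint", kind = "continuous", range = 480),
    list(name = "scrub",           kind = "continuous", range = 360)),
  true_scales = c(tree_cover = 960, human_footprint = 3840),
  true_beta = c("(Intercept)" = -1.2, tree_cover = 1.0,
                human_footprint = -0.7, effort = 0.006),
  seed = 7)
stack    <- generate_covariate_stack(cfg)
stations <- place_stations(cfg, seed = 8)
occ      <- simulate_detections(stack, stations, cfg, seed = 9)
mat      <- detection_matrix(cbind(clouded_leopard = occ$counts),
                             setNames(stations$effort, stations$station_id))
run_habitat_pipeline("clouded_leopard", stack, stations, mat)
```

```
<habitat_model> clouded_leopard: 3 scanned -> 3 screened -> 3 pruned terms
             term estimate adj_se      z      p importance scale_m
1     (Intercept)  -0.7126 0.3140 2.2692 0.0233     1.0000      NA
2          effort   0.0035 0.0024 1.4931 0.1354     1.0000      NA
3      tree_cover   0.9132 0.1072 8.5222 0.0000     1.0000     960
4 human_footprint  -0.5268 0.1041 5.0611 0.0000     1.0000    1920
5           scrub  -0.0072 0.0553 0.1298 0.8967     0.2719    7680
```

The generating covariates come back with importance 1.00 — tree cover at
exactly its true 960 m scale with β̄ = 0.91 (truth 1.0), human footprint
negative at the neighbouring 1920 m scale (smooth broad-scale fields make
adjacent radii nearly interchangeable) — while the noise layer is shrunk to
β̄ ≈ −0.01 with importance 0.27. `predict_surface(hm, stack)` then maps
p = e^z/(1+e^z) over the landscape (here ranging 0.014–0.94).

Temporal overlap between a nocturnal and a diurnal archetype:

```r
noct <- simulate_activity_times("nocturnal", 300, cfg, seed = 10)
diur <- simulate_activity_times("diurnal",   250, cfg, seed = 11)
smoothed_bootstrap_ci(noct, diur, B = 1000, seed = 12)
period_mass(fit_vonmises_kde(noct))
```

```
<overlap_result> nocturnal vs diurnal: Delta4 = 0.288 (n = 300, 250)
  95% smoothed-bootstrap CI [0.231, 0.347] (B = 1000)
  period hours mass_pct per_hour_pct
1   dawn     2     5.31         2.66
2    day    10    11.49         1.15
3   dusk     2     6.40         3.20
4  night    10    76.80         7.68
```

Both samples have ≥ 75 records, so the Δ₄ estimator is selected; the two
archetypes share about 29% of their activity density, and the nocturnal
species puts 77% of its activity mass into the 10 night hours (7.7% per
hour, versus a uniform 4.2%).

The staged pipeline (`run_pipeline()` or
`Rscript inst/scripts/run_pipeline.R --stage all --out output --seed 1`)
writes station/detection CSVs, covariate and occurrence-probability grids,
habitat-model, activity, overlap and co-occurrence report tables, plus a
`run_meta.json` with the configuration hash, seed and thresholds in effect.

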