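# camtrapdiel

Analysis of circadian (diel) activity patterns from camera-trap detection
records, for ecologists studying when species are active and how
predator and prey schedules relate.

Camera traps detect animals only while they move, so the temporal density
of detections is a proxy for activity. `camtrapdiel` implements the full
analysis chain on top of that idea:

* **Independent events** — greedy per-species, per-camera thinning so
  consecutive retained detections are at least 1 h apart (configurable).
* **Solar anchoring** — sunrise/sunset from the standard solar-position
  equations (zenith 90.833°, ±2 min); each detection becomes a signed
  offset from its solar anchor (before noon → sunrise, from noon →
  sunset; positive in daylight, negative at night), e.g. 22:10 with
  sunset 20:00 → −2 h 10 min.
* **Diel classification** — dawn/day/dusk/night partition (dawn and dusk
  are the hour each side of sunrise and sunset), duration-normalised
  rates, labels nocturnal / diurnal / crepuscular / cathemeral.
* **Activity overlap** — von Mises kernel densities with the plug-in
  bandwidth rule; overlap coefficient Δ = ∫ min(f̂ₐ, f̂ᵦ) via the grid
  (Δ̂₁) or density-ratio (Δ̂₄) estimator; 95 % CIs from 1,000 bootstrap
  resamples; categories low (< 0.5), moderate (0.5–0.75), high (> 0.75).
* **Predator–prey lags** — circular cross-correlation of 24-bin hourly
  profiles (all bins at every lag, df = 22), significance by
  t = r√((n−2)/(1−r²)) against the one-tailed critical value 1.72,
  significant-lag ranges and peak lag.
* **Seasonal comparison** — one-way ANOVA of solar offsets across
  seasons with Tukey HSD post hoc tests.
* **Synthetic data** — a generator of camera-trap scenes with von Mises
  mixture activity anchored to the actual solar cycle, plus analytic
  ground truth (true Δ by quadrature, true lags) for validation.

## Worked example

```r
library(camtrapdiel)

scene <- simulate_detections(seed = 7)            # default 4-site, 20-camera scene
cfg   <- analysis_config(scene$detections, scene$sites,
                         bootstrap_reps = 200, seed = 3)
res   <- run_all(cfg)

res$classification[res$classification$species == "fox", 1:2]
#>   species     class
#> 3     fox nocturnal

res$overlap[res$overlap$season == "annual",
            c("predator", "prey", "delta_pct", "ci_low_pct", "ci_high_pct", "category")]
#>       predator       prey delta_pct ci_low_pct ci_high_pct category
#> 1          fox       hare        71         65          77 moderate
#> 6          fox     rabbit        66         59          71 moderate
#> 11         fox wood_mouse        72         65          79 moderate
#> 16 pine_marten   squirrel        14         12          18      low
#> 21 pine_marten wood_mouse        88         82          92     high
```

The overlap rows read as Δ in percent with the bootstrap 95 % CI: in this
synthetic scene fox activity overlaps hare activity by 0.71 (moderate —
both are night-and-twilight active, but the fox is more strictly
nocturnal), while the nocturnal pine marten and the diurnal squirrel
barely overlap (0.14, low). `res$ccf` lists, per pair and
season, the ranges of lags at which the shifted predator profile correlates
significantly with the prey profile and the peak lag; `res$seasonal_anova`
gives each species' F-test for seasonal change in solar offsets.
`write_reports(res, "out/")` writes all tables as CSV.

A thin command-line wrapper with `simulate` / `analyse` / `report`
subcommands is installed at `inst/cli/camtrapdiel.R`.

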