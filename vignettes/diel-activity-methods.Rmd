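---
title: "Methods: diel activity, overlap and predator-prey lag analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel activity, overlap and predator-prey lag analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapdiel)
```

## The problem

Camera traps record the clock time of every animal detection, and because an
animal can only trigger a camera while it is moving, the temporal density of
detections is a usable proxy for a species' circadian (diel) activity
pattern. This package turns raw detection tables into that analysis:
independent activity events, activity profiles anchored to the solar cycle,
diel classification, pairwise temporal-niche overlap, and lagged
cross-correlation between predator and prey activity.

## Detection events

Camera bursts and lingering animals inflate raw image counts, so detections
of the same species at the same camera are thinned to *independent events* by
a greedy forward scan: the first record is kept, and each later record is
kept only if it falls at least the independence interval (default 1 h) after
the most recently *kept* record. Scanning against the last kept record (not
the last raw record) is the standard camera-trap convention and is what
guarantees that all retained consecutive events are separated by at least the
interval; it also makes the filter idempotent and monotone in the interval.
A multi-animal image is a single event, and images of the same species at the
same camera within the same minute are collapsed as bursts.

Predator-prey comparisons are restricted to locations where both members of
the pair were detected, so that a temporal comparison is not confounded by
the two species simply living in different places. The location unit
defaults to the broad study site rather than the individual camera.

## Solar anchoring

Sunrise and sunset are computed from the standard general solar-position
equations (Julian-century polynomials for the solar declination and the
equation of time, zenith 90.833 degrees so that refraction and the solar
disc are included), with one refinement pass at the event time. Agreement
with an independent elevation-crossing computation is within 2 minutes,
which is negligible against the 1-h resolution of the analysis. Polar
latitudes are rejected rather than approximated. Camera timestamps are
treated as fixed-offset local civil time; the site table carries the UTC
offset, and no daylight-saving reinterpretation is applied — if the source
data switch clocks mid-study the caller should normalise them first.

Each detection is expressed as a signed offset from a solar anchor:
detections with clock time before 12:00 are offset from sunrise, those from
12:00 onwards from sunset; the sign is positive for daylight detections and
negative otherwise. So a detection at 22:10 with sunset at 20:00 has an
offset of −2 h 10 min, i.e. nocturnal activity. Offsets keep minute
precision throughout (the rule's worked example is minute-precise, and
rounding to whole hours would only discard information).

The 24-h circle is partitioned into dawn `[sunrise−1 h, sunrise+1 h)`, day
`[sunrise+1 h, sunset−1 h)`, dusk `[sunset−1 h, sunset+1 h)` and night
`[sunset+1 h, sunrise−1 h)`. Intervals are half-open (closed at their
start), which is the only convention under which the four periods tile the
circle exactly; the night period is the complement of the other three.
Seasons are meteorological: March–May, June–August, September–November,
December–February.

## Activity profiles and diel classification

Hourly profiles count events in 24 bins beginning at the hour mark
(11:00–11:59 is one bin). For plotting, frequencies are min–max normalised,
$z_i = (x_i - x_{min})/(x_{max} - x_{min})$; a constant profile maps to all
zeros by convention (the formula is otherwise undefined there).

A species is classified by the diel period in which it is most active. Dawn
and dusk are pooled into a single crepuscular period before comparison —
without pooling, a bimodal dawn-and-dusk species could never win either
window alone and crepuscularity would be unreachable. Because period
durations differ (and drift seasonally), raw tallies are converted to rates
(events per hour of period) using the mean period durations over the solar
days represented in the data. The label is the arg-max rate; when the top
rate does not exceed the runner-up by a dominance factor (default 1.25) the
species is called cathemeral. The dominance factor is this package's
convention — the classification rule itself has no tie-break — and 1.25 was
chosen once as a value that separates genuine preference from sampling
noise at a few hundred events; it is exposed as a parameter.

## Overlap estimation

Detection clock times are mapped to angles and smoothed with a von Mises
kernel. The kernel concentration comes from the von Mises plug-in rule:
the data's concentration $\hat\kappa$ is estimated from the trigonometric
moments of orders 1–3 (taking the largest implied concentration — the
first moment alone collapses for bimodal dawn/dusk samples whose modes
nearly cancel), and the kernel concentration is
$\nu = \left[\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}{4 \sqrt{\pi} I_1(\hat\kappa)^2}\right]^{2/5}$,
optionally divided by an adjustment constant $c$ (default 1; 0.8 sharpens,
mirroring common practice for the grid estimator). Densities are evaluated
on a 128-point grid and renormalised so the trapezoidal integral is exactly
one, which keeps very concentrated samples well behaved on a finite grid.

The overlap coefficient $\Delta = \int \min(f_a, f_b)$ is estimated either
by the grid rule ($\hat\Delta_1$: trapezoid of the pointwise minimum of the
two fitted densities) or by the density-ratio rule ($\hat\Delta_4$: mean of
$\min(1, \hat f_{other}/\hat f_{own})$ over the observed points, averaged
over both samples). Following the reference estimator literature,
$\hat\Delta_1$ is used when the smaller sample has fewer than 50 events and
$\hat\Delta_4$ otherwise; both are exposed. Confidence intervals come from
1,000 bootstrap resamples of each species' times (with replacement, original
sample sizes, bandwidth re-estimated per resample) and the percentile
2.5/97.5 interval. The percentile interval was chosen as the simplest
reproducible default; the resampling unit is the detection time, not the
camera, since the analysis treats events as exchangeable draws from the
species' activity density. Overlap below 0.5 is labelled low, 0.5–0.75
moderate, above 0.75 high; both boundary values are moderate.

## Lagged cross-correlation

Predator and prey hourly-count profiles are compared by a circular
cross-correlation: for each lag $h$ from −12 to +11 the predator profile is
rotated by $h$ hours (wrap-around, so all 24 bins enter at every lag and the
degrees of freedom stay $n-2 = 22$) and Pearson-correlated with the prey
profile. Raw counts enter the CCF; since Pearson correlation is invariant
to location and scale, using the normalised $z_i$ instead would give the
same $r$. Significance of each $r(h)$ uses
$t = r\sqrt{(n-2)/(1-r^2)}$ against the one-tailed critical value at
$p = 0.05$ with 22 df (1.72), applied to $|t|$ in the direction of the
observed sign; a two-sided option is available. Reported are the maximal
runs of consecutive significant lags and the peak lag — the significant lag
of largest $|r|$, with ties broken towards the smallest $|h|$ and then the
negative lag (a package convention; ties are vanishingly rare on real
profiles).

## Seasonal offset comparison

Within a species, the signed solar offsets (decimal hours) are compared
across seasons by classical one-way ANOVA with post hoc Tukey HSD
(Tukey–Kramer for the unequal seasonal counts typical of camera-trap data,
where a species may have hundreds of spring events and a handful of winter
ones). Seasons with fewer than two events are dropped with a warning. No
normality or variance gatekeeping is enforced — offsets are bounded,
many-sample and analysed descriptively — but group summaries are returned
for inspection.

## The synthetic generator and what it does (not) show

`simulate_detections()` generates detection tables with known truth. Each
species is a von Mises mixture on the 24-h circle whose components are
anchored to *solar events* (sunrise, sunset, the midpoints of day and
night), so the clock-time density drifts through the year the way real
activity anchored to photoperiod does; this is what makes the seasonal
offset analysis testable. Counts per camera-day are Poisson at the
template's daily rate. The default scene — four sites around 54–55° N,
20 cameras, four 14-day windows (one per season), ten species in three
guilds with rates ranked like a multi-survey collation — was fixed once as
a realistic desk-scale design and produces a few thousand events.

Ground truth (analytic densities, true overlap by ≥4,096-point quadrature
cross-checked trapezoid-vs-Simpson, true rotation lags) accompanies every
scene. Validation sample sizes were likewise fixed once at values typical
of per-species camera-trap samples: 1,000 events/species for overlap
recovery, 500 for peak-lag recovery, 200 for guild classification and for
bootstrap-coverage checks.

The generator deliberately omits imperfect detection, camera failure,
serial correlation from individual movement, and abundance drift. Passing
its tests therefore demonstrates that the estimators recover the activity
structure they model, not that field data are free of those confounds —
in particular, everything downstream rests on the working assumption that
detection frequency reflects activity, uncorrected for detectability.

## Numerical choices

* Von Mises densities use exponentially scaled Bessel functions, so
  point-mass-like samples (huge concentration) do not overflow.
* The concentration inverse $A_1^{-1}$ uses the standard piecewise
  approximation; higher-moment inversions are solved by bracketed
  root-finding, capped at $\kappa = 2000$.
* Overlap estimates are clipped to $[0, 1]$; grid densities are
  renormalised before integration.
* Constant profiles are an error in the CCF (correlation undefined), a
  zero-vector in normalisation, and all-zero counts with a warning in
  empty profiles.
* All stochastic steps (simulation, bootstrap) are seeded; the same seed
  reproduces a scene and a report byte for byte.

## Known limitations

* Polar and near-polar deployments are unsupported.
* The bootstrap ignores any clustering of detections within cameras.
* The cathemeral dominance threshold is a convention, not an estimate; on
  genuinely borderline species the label is sensitive to it.
* Sub-minute timing information is discarded by design.
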