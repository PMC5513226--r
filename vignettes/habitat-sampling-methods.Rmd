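---
title: "Testing nest-site habitat sampling from GPS telemetry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing nest-site habitat sampling from GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the analysis

If ground-nesting birds choose nest sites by sampling habitat during the
weeks before laying, their prenesting movements should concentrate near the
eventual nest site as laying approaches. `nestmove` operationalizes that
prediction for GPS-tracked wild turkey females: every hourly movement
segment in the 45 days before the first egg is classified as interacting
(1) or not (0) with a set of nest-associated buffers, and the probability
of interaction is modelled against the days-before-laying index. Under
habitat sampling the interaction probability should rise toward laying
(negative slope on days-before-laying); without it the series is flat.

All coordinates are planar meters (a projected system such as UTM); every
distance and area in the package is Euclidean. Dates are handled at daily
resolution for phase logic and full timestamps for segments. The midnight
roost fix belongs to the calendar day it closes — it is the roost of the
preceding evening.

## Phase delineation

*Incubation onset* is the earliest day on which **every** fix lies within
`incubation_radius_m` (default 50 m) of the nest and that opens a run of at
least `incubation_min_run` (default 2) consecutive such days. The
single-day rule (`incubation_min_run = 1`) is available, but one quiet or
noisy day can then masquerade as onset; in the field the delineation is
cross-validated against VHF checks that a desk pipeline does not have, so
the run guard is the default here.

*Laying onset* is the first day of the run of consecutive nest-visit days
(at least one daytime fix within `laying_visit_radius_m`, midnight roost
outside it) that ends the day before incubation onset. The visit radius
defaults to the incubation radius; no separate value is established for it.
When no visit signature exists — sparse schedules, noisy data, or a
simulated bird that simply never shows one — laying onset falls back to
incubation onset and the fallback is logged. Phase windows are half-open at
day resolution: prenesting is `[laying − 45 d, laying)`, laying is
`[laying, incubation)`.

The 10-m GPS-accuracy exclusion applies to incubation-period distance
summaries (where the bird is stationary and sub-10-m "movement" is
positional error), **not** to prenesting summaries: per-bird prenesting
minima below 10 m are real data in the published tables, and a global
exclusion would contradict them. The rule is a strict inequality — a fix at
exactly 10 m stays in.

## Utilization distributions

Prenesting ranges use a dynamic Brownian bridge movement model. The motion
variance σ²ₘ (m²/s) is estimated by leave-one-out maximum likelihood: each
interior fix is compared with the bridge spanned by its neighbours, whose
variance at relative time α is

    T σ²ₘ α(1−α) + (1−α)² δ² + α² δ² [+ δ² for the left-out fix],

with δ the GPS location-error SD (default 10 m). Estimation slides a
`window` of 31 fixes along the track; each segment receives the mean of the
estimates from every window that holds it in its central, margin-trimmed
(margin 11) section, so the variance can change along the track at window
margins. The published estimator places behavioural change points at window
margins; this package's central-section averaging is a deliberate
simplification of that machinery and is the only part of the estimator not
reproduced literally. Tracks shorter than one window fall back to a single
global estimate with a logged warning.

The UD integrates the bridge density over each segment with two-point
Gauss–Legendre quadrature in α on `nt ∝ L/σ_mid` intervals. Midpoint
quadrature is visibly wrong here: near the segment endpoints the bridge SD
shrinks to the location error while the mean still sweeps L/nt meters per
interval, and the uncancelled boundary terms reach ~1% of the peak density.
Gauss–Legendre's O(h⁴) boundary error puts the two-fix UD within 1e-4 of a
2000-point reference.

Incubation ranges use a fixed isotropic Gaussian kernel with the
normal-scale reference bandwidth per axis averaged to one isotropic value,
`h = mean(sd(x), sd(y)) · n^(−1/6)`. At least five non-coincident points
are required unless a bandwidth is supplied.

Grids default to cell = max(5 m, extent/400) with a 3-SD (or 3-bandwidth)
padding margin: published range areas span 37–24,000 ha, so no fixed
resolution suits both ends. Isopleth **areas** are cell counts above the
mass threshold (the k highest-mass cells whose masses sum to the level), so
the contained mass is the level to within one cell by construction, and a
plateau UD encloses level × support rather than the whole plateau.
Isopleth **polygons** are traced with marching squares, at a level strictly
between the threshold and the next larger distinct cell value — contouring
exactly at the threshold is ambiguous wherever grid nodes tie with it
(symmetric UDs tie in whole rings) and then yields duplicate rings that
break even-odd containment. Points on a polygon boundary count as inside.

## Buffers and segment classification

Five regions per female: the equal-area circle of the 95% incubation
kernel (r = √(A/π)), the 75% incubation-kernel polygon, a circle at the
population mean incubation distance (70.82 m Rio Grande, 55.24 m Eastern),
and fixed 100- and 500-m circles. All circles are centered on the nest.
When no incubation UD can be fitted, the two kernel-based regions are
omitted and logged.

A segment is classified 1 against a region when the closed straight segment
touches the closed region — crossing **or** full containment. A segment
wholly inside a nest buffer is biologically an interaction; a pure
boundary-crossing semantics is available via `intersection_mode =
"boundary"`. Segments are formed only between consecutive fixes that are
both in prenesting days (segments spanning a phase boundary are dropped
rather than split — splitting would invent a fix), and each segment carries
the day of its starting fix. Circle classification reduces to the
point-to-segment distance; polygon classification to edge crossings plus
even-odd endpoint containment, verified against a dense-sampling oracle.

## Inference

The unit of analysis is the segment, pooled over females within a
population, mirroring the study design this package reimplements. The
logistic model is fitted by `stats::glm`; complete separation and constant
outcomes are errors, and the score's sup-norm at the optimum is stored so
calibration is checkable. Windowed odds ratios use the direct 2×2 formula
with the Woolf log-interval (z = 1.96) and the Haldane–Anscombe 0.5 added
to every cell only when some cell is zero (flagged). Windows default to
1–5 / 6–15 / 16–45 days before laying; the day-closest tie-break takes the
day nearer laying. The Welch two-sample comparison uses `stats::t.test`
with Satterthwaite degrees of freedom.

Pooling segments ignores that consecutive hourly segments of one female are
serially dependent. On simulated null populations the naive Wald interval
for the slope covers zero in only ~75% of replicates — the estimate is
essentially unbiased but its true sampling SD is ~1.6× the naive SE.
`fit_intersection_model(..., cluster_se = TRUE)` therefore provides
bird-clustered robust standard errors (`sandwich::vcovCL`), used with a t
quantile on birds−1 degrees of freedom; that interval is calibrated (~95%
coverage) and is what the package's own specificity and power checks use.
The naive interval remains the default output because it is the analysis
being reimplemented; treat its p-values as anticonservative.

## The synthetic-data generator

`sim_config()` encodes the monitoring design: fixes hourly 0600–2000 plus
one midnight roost fix (a 2-h schedule is supported; the study hardware
recorded 2-h fixes while the analysis speaks of hourly segments, so the
schedule is a config choice defaulting to hourly), 45 prenesting days,
10–14 laying days with one daily nest visit and the roost elsewhere, 26–28
incubation days with every fix at the nest, and isotropic GPS error on
every emitted position (default σ = 10 m, the value behind the 10-m
accuracy exclusion).

Movement is a biased correlated random walk: gamma step lengths (shape 2,
scale 100 m — mean 200 m per move, a plausible hourly displacement for a
prenesting female), wrapped-Cauchy turning angles (ρ = 0.5), and weight 0.1
pulling each step toward the range center. Three roost sites sit within
700 m of the center (kept ≥ 120 m from the nest so a laying-day roost can
never sit inside the visit radius); the nest is offset exponentially
(mean 400 m) from the center. Each bird draws from its own stream seeded
from the master seed and the bird index, so per-bird output survives
reordering. The walk is burned in for 30 full daily cycles — daytime steps
plus the nightly roost snap — because the tracked process equilibrates
under both jointly, and a walk-only warmup leaves a residual day trend in
the null world (a spurious habitat-sampling signal). Incubation failures
(2%/day) can occur from the third incubation day; attempts failing before
the onset rule can register would be unobservable in the field too.

`habitat_sampling = "sampling"` plants the behavior under test: on the day
d before laying, the female makes a nest-area visit (one daytime fix within
~20 m of the nest) with probability 0.6·exp(−(d−1)/12) — about 0.15/day
averaged over the window, concentrated in the last two weeks. Under
`"none"` the nest plays no role in prenesting movement, so the day of
closest approach is uniform over the window by exchangeability.

What the generator does **not** emulate: habitat structure and vegetation,
predation risk fields, renesting chains, inter-bird interactions, schedule
gaps and fix failures, and anisotropic or state-switching movement. Passing
recovery tests on this generator shows the pipeline detects (and refuses to
hallucinate) a movement signature of the posited strength under the study's
monitoring design — not that real turkeys behave like the generator.

## Problem sizes and verification

The test suite verifies the machinery against independent oracles: the
segment classifier against dense sampling along the segment (1000 random
instances), the logistic MLE against a coarse-to-fine grid search of the
likelihood, the windowed OR against the exponentiated coefficient of a
window-indicator logistic fit, kernel UDs against direct summation of
per-point Gaussians, isopleth areas against the χ²₂ closed form for a
Gaussian UD, and the two-fix bridge against fine quadrature of the analytic
density. Aggregating the two published per-bird tables (21 and 23 females)
reproduces their printed population footers exactly at printed precision.

Monte-Carlo checks run at 100 replicates of 20 birds for power and
specificity, 100 birds for onset recovery, and 500 replicates for the null
type-I rate — sizes chosen so the whole suite completes in a few minutes
while keeping binomial noise on a 90–95% rate near one point. Two
published-table quirks are carried as data, not reconciled: the Eastern
mean minimum distance and the Eastern 99%-range footer do not recompute
exactly from their own printed columns (the recomputed values are reported),
and the tables label dispersion "SD" while the accompanying text calls the
same numbers "SE" — this package reports SDs over birds.

## Known limitations

- Segment pooling without random effects is inherited from the analysis
  being reimplemented; use the cluster-robust option for calibrated
  uncertainty.
- The dBBMM change-point machinery is simplified to margin-trimmed window
  averaging of σ²ₘ.
- Kernel bandwidth is the reference rule only; no cross-validated or
  anisotropic bandwidths.
- No geodesy: inputs must already be planar meters.
- Censored entries ("<1") in external tables are carried as bounds with
  flags and excluded from mean recomputation.
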