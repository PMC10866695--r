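---
title: "Stability landscapes, transition potential and moisture tracking: methods"
author: "ecotip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability landscapes, transition potential and moisture tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotip)
```

This vignette documents the models and numerical choices behind
`ecotip`: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the known limitations.

## 1. Alternative stable states and potential analysis

### Model

Tree cover $T \in [0, 100]$ % is treated as the state variable of a
system whose effective potential depends on a climatic driver $c$ (mean
annual precipitation, MCWD, or dry-season length). Under the standard
assumption that the spatial ensemble of pixels at a given $c$ samples
the stationary distribution of the underlying stochastic dynamics, modes
of the conditional density $f(T \mid c)$ are stable equilibria and
antimodes are unstable equilibria. This "space-for-time" reading is the
central, untestable-from-within assumption of the method: spatial
bimodality is consistent with bistability but can also arise from
unresolved environmental heterogeneity (soils, fire history,
floodplains). The package therefore reports equilibria and thresholds,
not basin depths or exit times (out of scope by design).

### Estimation

For each window centre $c_k$ along the driver axis, pixels with
$|c - c_k| \le w$ are pooled and the density of their tree cover is
estimated with an exact Gaussian-sum kernel density estimator on a fixed
grid (0–100 % in 0.5 % steps),
$$\hat f(g) = \frac{1}{n h}\sum_i \phi\!\left(\frac{g - x_i}{h}\right),
\qquad h = 1.06\,\sigma\,n^{-1/5}.$$
The sum is evaluated exactly (in compiled code) rather than through a
binned FFT: mode detection differentiates the density profile, and
binning artefacts of the same order as the density floor would corrupt
it. The bandwidth follows Silverman's rule of thumb in its standard
form; note the exponent is $n^{-1/5}$ — a bandwidth *growing* with
sample size is not meaningful. No boundary correction is applied, and a
maximum at 0 or 100 % is a legitimate equilibrium because tree cover is
physically bounded (clipped draws pile up there).

### Mode filtering

Two filters remove spurious equilibria:

* a **density floor** (default 0.005): local maxima with density below
  it are ignored;
* a **dimensionless sensitivity** (default 0.005): a maximum is kept
  only if its topographic prominence — height above the higher of the
  two cols separating it from higher terrain — is at least the
  sensitivity times the global maximum density.

The prominence definition was an open design choice; it was selected
because it is dimensionless, matches the "higher value = stricter
criterion" behaviour, and (with prominences computed once on the
unfiltered peak set) makes the retained-mode count provably
non-increasing in the sensitivity, which `sensitivitySweep()` exploits.
Both defaults equal 0.005; whether they are one filter described twice
or two distinct ones is ambiguous in the source methodology, so they are
independent parameters set equal by default. Plateau maxima resolve to
their leftmost grid point; the deepest minimum between two retained
maxima (leftmost on ties) is the antimode.

### Windows

Window centres advance in 10 mm yr⁻¹ steps over 0–3500 mm for MAP,
10 mm over −800–0 mm for MCWD, and 0.1 month over 0–12 for DSL. The
half-widths are not prescribed by the source methodology; defaults of
50 mm (MAP), 25 mm (MCWD) and 0.5 month (DSL) keep each window at least
five increments wide — enough pixels for a stable density (with
$n_{\min} = 100$ per window) while resolving thresholds at the ±50 /
±30 / ±0.5 tolerances used in validation. The half-width is the leading
term of the threshold-recovery bias: a window centred just outside the
bistable band still pools some bistable pixels, so recovered edges sit
up to one half-width outside the truth (980/1820 mm for a 1000/1800 mm
truth is typical).

### Threshold extraction

The axis is oriented so larger = wetter (DSL is negated internally).
States are split at 50 % tree cover into "low" and "high"; the split
only needs to fall between the two modes (20 % and 85 % by default) and
is configurable. The lower critical threshold is the dry edge of the
contiguous run of high-state windows anchored at the wet end of the
landscape; the upper critical threshold is the wet edge of the low-state
run anchored at the dry end; anchoring suppresses isolated spurious
windows. The bistability range is the longest contiguous bimodal run,
with fragmentation flagged rather than silently merged.

## 2. Climate metrics

* **MAP**: mean over years of annual precipitation totals.
* **MCWD**: within each year, $WD_1 = \min(0, P_1 - E)$,
  $WD_m = \min(0, WD_{m-1} + P_m - E)$; the year's MCWD is the most
  negative $WD_m$. The reference evapotranspiration is fixed at
  $E = 100$ mm month⁻¹, the conventional tropical value; the source
  methodology never defines its MCWD variant, and its drought layer may
  have used actual evapotranspiration. $E$ is a parameter
  (`evapRef`) so either convention can be run; results shift with $E$
  roughly linearly in dry-season length.
* **DSL**: count of climatological months strictly below 100 mm (the
  conventional tropical dry-month criterion; the threshold is a
  parameter). A month at exactly 100 mm is not dry. `computeDSL()`
  returns integers; the synthetic DSL *axis* is kept continuous (an
  effective climatological dry-season length) so that threshold recovery
  is not quantised to whole months.
* **Dry-season temperature**: July–October mean, per year.

## 3. Trends, screening and 2050 projection

Per-pixel OLS of annual values on calendar year, two-sided $p$ from the
slope's $t$ statistic, significance at $\alpha = 0.1$ with **no
multiple-testing correction** — deliberately mirroring the mapped
product this reproduces; the per-pixel maps are descriptive screens, not
inference. Under the null, 10 % of pixels are expected significant, and
the test suite checks exactly that rate.

Projection evaluates the fitted line at 2050 (not last observation +
slope × Δt): deterministic and noise-free, at the cost of ignoring any
curvature. A magnitude guard (default |slope| ≤ 25 mm yr⁻¹ yr⁻¹ for
rainfall) aborts on implausible significant slopes rather than silently
extrapolating them. Constant series get slope 0 with an undefined
$p$-value and are never significant.

Extreme droughts are years whose annual MCWD is at least 2 standard
deviations more negative than the reference mean, counted within
2001–2018 and capped at 5. The "historical" baseline is ambiguous in the
source; both the analysis window itself (default) and the full series
are selectable.

## 4. Stability classes and the transition-potential index

Classes partition pixels by MAP against the lower/upper thresholds
(defaults 1000/1800 mm yr⁻¹; the values recovered by the potential
analysis can be passed instead, making the pipeline self-consistent).
Bins are half-open with the wetter class winning on the boundary —
immaterial at 10-mm window resolution, but deterministic and documented.
Only the MAP axis drives classification; the MCWD and DSL landscapes are
reported alongside but not fused into the class map, because no fusion
rule is defined in the source methodology.

The index is the documented additive combination (×10 significant
dry-season temperature slope; 0/1/2 class score; 0.2 per drought event;
+1 within 10 km of a road; −1 inside protected areas or Indigenous
territories), masked over deforested and savanna-biome pixels. With
observed slopes in [−0.01, 0.06] °C yr⁻¹ the theoretical envelope is
[−1.1, 4.6]; the published range "−1 to 4" corresponds to the
no-significant-trend corners, which the package reproduces exactly.
Categories follow the cumulative reading (low ≤ 1 < moderate ≤ 2 <
high), which reproduces the "more than 1 / more than 2 disturbance
types" logic; the figure-caption rule (low < 0, moderate 1–2, high > 2)
leaves [0, 1) unlabelled and is available as an alternative with that
interval mapped to low. Synergies between disturbances are explicitly
not modelled. Road distances are great-circle point-to-segment values
computed against vertex-interpolated polylines (0.5 km spacing; chord
error at the 10-km boundary is metres), because a planar approximation
on a geographic grid biases exactly the cells near the buffer edge.

## 5. Moisture tracking

A deliberately simplified, single-layer forward Lagrangian tracker:
parcels are released in proportion to evapotranspiration (100 per mm),
advected by bilinear interpolation of a single wind field in 0.1-h
steps, and deposit the fraction $P\,\mathrm{d}t / \mathrm{TPW}$ of their
moisture at each step. Termination at 1 % residual moisture or 720 h.
The published model this emulates uses 25 vertical ERA5 layers with
vertical shuffling; the single-layer simplification preserves the
properties the package asserts — exact budget closure
(released = allocated + exited + residual to round-off) and the
closed-form downwind decay length $L = u\,\mathrm{TPW}/P$ on uniform
forcing — but not realistic trajectories, so country-to-country
percentages from real reanalysis are out of scope. Flow fractions are
computed on the *tracked* moisture in each target region, not observed
rainfall; with synthetic forcing the two differ, and the convention is
stated on the `FlowMatrix` container. The 10 % reporting filter is a
display convention, flagged but never applied to the stored numbers.

## 6. The synthetic-data generator

The generator defines the study conditions; it is not tuned per test.

* **Tree cover** is a conditional two-component Gaussian mixture:
  savanna mode 20 ± 10 %, forest mode 85 ± 8 %, clipped to [0, 100].
  Below the dry threshold only the savanna mode exists; beyond the wet
  threshold only the forest mode; in between a pixel is forest with
  probability 0.5. A mixture (not a mechanistic hysteresis model) is
  used because cross-sectional data cannot distinguish the two and the
  potential analysis consumes only conditional bimodality. The mode
  parameters keep both modes above the 0.005 density floor for windows
  of ≳ 1000 pixels. Encoded truths: 1000/1800 mm (MAP axis),
  −450/−350 mm (MCWD axis), 5/8 months (DSL axis). The default grid is
  250 × 400 = 10⁵ pixels with the driver laid as a west–east gradient
  with within-column jitter (marginally uniform over the axis range, so
  every window is equally populated).
* **Climate cubes**: monthly climatology (an Amazon-like seasonal
  cycle, ~2260 mm yr⁻¹ with a July–October dry season) + linear year
  trend + Gaussian noise, precipitation truncated at zero. The default
  temperature trend 0.027 °C yr⁻¹ reproduces the observed 0.27 °C
  decade⁻¹ dry-season warming; injected slopes are recorded as ground
  truth for recovery tests. Truncation at zero slightly biases trends
  where climatology is small relative to noise — kept, because
  non-negativity is physical; noise defaults are small enough that the
  bias is negligible in tests.
* **Disturbances**: drought counts are truncated Poisson (λ = 1.5,
  capped at 5, mirroring the 0–5 event range); roads are random-walk
  polylines (only distance-to-road matters downstream); protection and
  deforestation masks are disjoint random cell samples hitting their
  target fractions exactly.
* **Not emulated**: satellite tree-cover error structure, spatial
  autocorrelation of disturbance, river/floodplain geomorphology,
  scenario-driven (CMIP-like) climate fields. Passing tests therefore
  demonstrate that the estimators recover known structure under the
  stated noise model — not that real-data products are correct.
* The generator treats tree cover as being in equilibrium with the
  climatological normal; the mismatch between a single tree-cover epoch
  and a multi-decade climate normal in the real data chain is thereby
  assumed away.

## 7. Problem sizes, determinism and I/O

Validation uses 10⁵-pixel biomes with 20-seed medians for threshold
recovery (the package's chosen reference scale; recovery error is
dominated by the window half-width well before sampling noise at this
size), a 50 × 50 forcing with ~10⁴ parcels for the moisture budget, and
10⁴ pixels for significance-rate checks. Every generator takes an
explicit integer seed and is bit-reproducible; `runPipeline()` threads
one master seed through all stages and serialises the exact
configuration next to its outputs.

Rasters are read and written as plain-text ESRI ASCII grids at full
double precision (value-identical round trips, NA-mask preserved),
roads as GeoJSON LineStrings, tables as CSV and reports as JSON. All
layers of a run must share one `GridSpec` (geographic lon/lat,
pixel-centre registration, north-to-south rows); a nearest-neighbour
regridder is provided for pre-harmonisation but warns, since
nearest-neighbour resampling is not area-conserving. The package's
programmatic interface (and `runPipeline()`) is the intended entry
point; there is no shell executable.

## 8. Known limitations

* Space-for-time substitution (above) — thresholds are associative, not
  demonstrated tipping points.
* Threshold recovery bias of order one window half-width; halving the
  half-width trades it against density noise.
* The index is additive with fixed weights; no interaction terms.
* Single-layer moisture tracking; no vertical structure, no backward
  runs.
* No uncertainty propagation from tree-cover measurement error into the
  landscapes (no weighting scheme is defined for it).
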