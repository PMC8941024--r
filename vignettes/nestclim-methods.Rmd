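---
title: "Methods: microclimate QC, agreement, and the nest-development comparison battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microclimate QC, agreement, and the nest-development comparison battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestclim)
```

## The problem

Founding *Atta sexdens* queens seal themselves into a first excavated chamber
(the claustral phase) and rear brood and a fungus garden on body reserves
alone. Whether that chamber sits in full sun or under shade changes the solar
energy reaching the soil, the temperature regime around the chamber, and
ultimately queen survival and colony development. `nestclim` implements the
complete processing chain such a field comparison needs: solar-geometry
limits for irradiance quality control, daily integration of 5-minute
pyranometer records, agreement scoring between paired microclimate series,
chamber geometry, and the statistical comparison battery — together with a
synthetic-data generator that stands in for the (undeposited) field
recordings so every stage can be exercised and tested end to end.

## Solar geometry and the physically possible limits

For a site latitude $\Phi$ (signed; the default $-22.85^\circ$ encodes a
southern-hemisphere site printed unsigned as 22.85), day of year $D$ and
decimal clock hour $H_d$, the package computes

* the angular fraction of the year $F = 360^\circ D / 365$,
* the solar declination $\delta(F)$ and the Earth–Sun distance ratio $R(F)$
  from truncated Fourier series with fixed published coefficients,
* the hour angle $\omega = (12 - H_d)\,15^\circ$, and
* $\cos Z = \sin\delta \sin\Phi + \cos\delta \cos\Phi \cos\omega$,

giving the extraterrestrial irradiance
$I_E = 1361\,(1/R)\cos Z$ W/m². Three numerical choices deserve a note:

* **The zenith identity.** The right-hand side above is the standard
  cosine-of-zenith identity, and the irradiance formula consumes
  $\cos Z$; the function is therefore named and implemented as `cos_zenith()`
  rather than returning the angle itself.
* **The second harmonic of $R$.** The distance-ratio series alternates sine
  and cosine harmonics; its $2F$ term is implemented as
  $-0.0001489\,\sin(2F)$, consistent with the neighbouring $\sin(3F)$ and
  $\cos(4F)$ terms. The coefficient is small ($\sim 10^{-4}$), so either
  reading changes $I_E$ by well under 0.1%.
* **Night.** $\cos Z < 0$ means the sun is below the horizon;
  `extraterrestrial_irradiance()` floors the result at 0 so it can serve
  directly as a physical ceiling. No equation-of-time, longitude, refraction
  or atmospheric-transmittance correction is applied: $H_d$ is taken as the
  logger's clock time.

Quality control accepts a 5-minute sample only if it is *strictly* above
0 W/m² and *strictly* below its ceiling: $1.20\,I_E$ for global horizontal
irradiance (transient multireflection from scattered clouds can push ground
readings up to 20% above the extraterrestrial value) and $I_E$ for the
diffuse component. Strictness at both boundaries is deliberate: a reading of
exactly 0 carries no energy and a reading exactly at the ceiling is as
suspect as one above it. A consequence worth knowing is that night-time
zeros are rejected (as non-positive) rather than accepted; daily totals are
unaffected since their contribution would be zero either way.

Accepted samples are numerically integrated per day and component:
$E = \sum v_i \cdot 300\,\mathrm{s} / 10^6$ MJ/m². Rejected samples are
treated as missing — never interpolated — and each day carries a `coverage`
fraction so callers can drop poorly covered days; the default threshold is 0
(keep everything), recording rather than guessing how partially lost days
should be totalized. Sample spacing is fixed at 300 s and irregular
timestamps are an error, not a silent reweighting.

## The Willmott index of agreement

For paired series $A$ (evaluated) and $B$ (reference), with
$A'_i = A_i - \bar B$ and $B'_i = B_i - \bar B$,

$$d = 1 - \frac{\sum_i (A_i - B_i)^2}{\sum_i \left(|A'_i| + |B'_i|\right)^2}
\in [0, 1],$$

with $d = 1$ for identical series and $d = 0$ for no agreement. The
denominator is the potential-error form of Willmott (1981): centring on the
reference mean and *summing* the absolute deviations. A transcription of the
formula sometimes circulates with $\sum(|A_i| - |B_i|)^2$ in the
denominator; that variant is undefined (0/0) for identical series —
contradicting the index's defining property — and unbounded below, so it is
kept only behind `willmott_index(..., form = "printed")` for auditability
and used nowhere else. When the denominator is exactly zero (both series
constant and equal to $\bar B$) the series are identical and $d = 1$ by
convention. The index is invariant under a common additive shift of both
series but not under scaling; callers must state which series is the
reference, and `monthly_willmott()` records the pair ordering and the sample
size $N$ per month.

## Chamber geometry

The initial chamber is modelled as a cylinder with a rounded roof:
$V = \pi r^2 (c_h + 0.67\,r)$ with cylinder height $c_h = h - r$. At
$h = r$ the formula degenerates to the cap alone, $0.67\,\pi r^3$, within
0.5% of a true hemisphere $\tfrac{2}{3}\pi r^3$ — exactly the gap between
the empirical 0.67 and $2/3$, which is why the package's hemisphere check
uses a $\le 0.5\%$ bound. Field tables record chamber *width* and *length*
but no base radius; `chamber_radius()` defaults to the mean semi-axis
$r = (\text{width} + \text{length})/4$, with `min`, `max` and `geometric`
reductions selectable, and `nest_volumes()` records the rule used. Reported
mean volumes are always means of per-nest volumes: the formula is nonlinear,
so the volume of mean dimensions is a different (biased) quantity.

## The comparison battery

* **Mortality** is compared with the test of equal proportions: a Pearson
  $\chi^2$ on the 2×2 deaths-by-environment table (1 df), optional Yates
  correction, via `stats::prop.test()`. For 91/100 vs 58/100 deaths this
  gives $\chi^2 = 28.66$ uncorrected and 26.95 with Yates.
* **Routing.** Each response is gated by a Shapiro–Wilk test
  (`stats::shapiro.test()`; the gate is plumbing, not a contribution, so it
  is delegated): $p \ge \alpha$ routes to ANOVA + Tukey, otherwise to the
  rank battery. Inside the pipeline the gate sees the *cell-centred*
  residuals rather than the pooled response: a strong environment effect
  makes the pooled sample bimodal and would otherwise make the parametric
  route unreachable for exactly the variables it suits best. A constant
  sample routes nonparametric (its W statistic is undefined).
* **Parametric branch.** `stats::aov()` on the environment × month
  factorial, Tukey HSD per factor, and a compact letter display (groups
  sharing a letter do not differ at $\alpha = 0.05$, the default
  everywhere).
* **Scheirer–Ray–Hare.** The pooled response is replaced by mid-ranks (which
  absorb ties), a factorial sum-of-squares decomposition is computed on the
  ranks, and each effect is tested with
  $H = SS_{\text{effect}} / MS_{\text{total}}$,
  $MS_{\text{total}} = SS_{\text{total}}/(N-1)$, against $\chi^2$ with the
  effect's df. $MS_{\text{total}}$ on mid-ranks equals
  $\tfrac{N(N+1)}{12}\bigl(1 - \sum(t^3 - t)/(N^3 - N)\bigr)$, so the tie
  adjustment is exact, and with one factor held constant $H$ reduces
  algebraically to the tie-corrected Kruskal–Wallis statistic — the package
  asserts this equivalence against `stats::kruskal.test()` to $10^{-9}$.
  Balanced designs (the study's intent: 25% of nests excavated per month)
  use the closed-form decomposition; unbalanced data fall back to type-II
  sums of squares from nested least-squares fits.
* **Dunn's test.** Pairwise post-hoc comparisons on the pooled mid-ranks,
  $z_{ij} = (\bar R_i - \bar R_j)/\sqrt{\sigma^2 (1/n_i + 1/n_j)}$ with
  $\sigma^2 = \tfrac{N(N+1)}{12} - \tfrac{\sum(t^3-t)}{12(N-1)}$, two-sided
  normal p-values, Benjamini–Hochberg adjustment by default, and a letter
  display from the adjusted p matrix. For two groups $z^2$ equals the
  Kruskal–Wallis $H$ exactly, which the tests use as an independent oracle.
* **Letters.** The display uses the insert-and-absorb algorithm: start from
  one letter shared by all groups, split on every significant pair, absorb
  redundant columns; groups are ordered by decreasing mean (parametric) or
  median (nonparametric), ties broken by label.

Per-variable routing in the pipeline defaults to the gate for the four
chamber dimensions, *forced* nonparametric for volume (volumes are products
of dimensions, hence right-skewed, and are conventionally compared as
medians with Dunn letters), and nonparametric for counts. All overridable
via `run_study(routing = ...)`.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes, at
the study's stated conditions:

* **Irradiance** (288 five-minute samples/day): the extraterrestrial
  envelope at $-22.85^\circ$ latitude over a four-month window starting at
  day-of-year 305 (a November founding, matching queens collected after the
  nuptial flights of late October–November), attenuated by a clear-sky
  transmittance (0.72) and a beta-distributed daily clearness index
  (shape 2.1, 1.25) with bounded within-day noise (sd 0.08). Noise is
  *multiplicative* on the envelope rather than additive, because that
  produces exactly the failure modes the QC tier is designed to catch; rare
  multireflection spikes (probability 0.01/sample) land at 1.21–1.35 times
  $I_E$, above both components' ceilings. These defaults put sunny monthly
  mean totals at ≈17–21 MJ/m² with day-to-day sd ≈6–8. The shaded sensor
  records screen-transmitted light as the diffuse component;
  `shade_transmittance = 0.25` is calibrated to the *measured* shaded
  totals (monthly means ≈2–8 MJ/m², i.e. a 70–90% reduction), not to the
  screen's nominal 50% rating — the measured totals are the ground truth
  the pipeline must reproduce, and the discrepancy is recorded here. Both
  environments share one daily clearness sequence in `run_study()`, as
  adjacent field plots share weather; this is what makes between-environment
  agreement high for temperature and low for irradiance.
* **Temperatures** (daily): external = environment baseline +
  irradiation-coupled anomaly + weather noise; internal (15 cm, in the
  chamber) = damped external anomaly (damping 0.20 sunny, 0.55 shaded —
  bare insolated soil buffers its mean but the shallow chamber under grass
  tracks the surface) + small noise, lag 0 days at the daily timescale.
  Internal sd is therefore well below external sd (≈1 vs ≈4 °C in the
  sunny plot), and internal–external agreement is higher under shade.
* **Colonies:** 100 founding queens per environment; each dies during the
  claustral phase with probability 0.91 (sunny) or 0.58 (shaded); 25% of
  nests are excavated per month. Every excavated nest yields chamber
  dimensions drawn around environment-specific means (shaded deeper and
  larger); surviving nests yield censuses: negative-binomial counts
  (dispersion `size = 8`; the source tables print means but no dispersions,
  so overdispersion is a documented config default) around monthly mean
  trajectories, queen mass interpolated *linearly* between its month-1 and
  month-4 anchors (658.5 → 229.45 mg), and fungus biomass interpolated
  *log-linearly* between 64.5 and 1354.9 mg (growth of a culture is closer
  to multiplicative than additive). The printed census sentence pairs those
  four numbers ambiguously; the generator follows their stated order
  (queen mass falling, fungus biomass rising), and only the qualitative
  direction matters to any test. Sunny counts and fungus mass are scaled by
  0.65; queen body mass is similar between environments.

What it does **not** emulate: within-day temperature cycles (temperatures
are daily), autocorrelated multi-day weather regimes (daily clearness is
i.i.d.), soil heat diffusion, sensor drift, predation or pathogen loss, and
spatial structure within plots. Passing tests therefore demonstrate that the
*pipeline* recovers the parameters and contrasts built into data with the
right marginal structure — not that the field data themselves would meet
any particular threshold.

## Operating characteristics and problem sizes

The suite checks the battery's statistical behaviour at sizes chosen to
give tight Monte-Carlo error at interactive runtimes: the rank test's
type-I error is estimated from 2000 replicates of a 2×4 factorial with 6
observations per cell (binomial sd ≈ 0.5 percentage points at a nominal 5%),
the Dunn/BH any-pair false-discovery proportion from 2000 three-group null
replicates of 10 observations each, and mortality recovery from 100 seeded
colony simulations. For the recovery check, each environment's death count
must fall in the central exact-binomial 95% acceptance region of its own
generating parameter ($\mathrm{Bin}(100, 0.91)$ and
$\mathrm{Bin}(100, 0.58)$), counted per environment: each region holds
≈96.6% of draws, so ≥93/100 per environment is the coherent expectation —
demanding *joint* containment would have expected coverage
$0.966^2 \approx 0.93$, the very edge of the same threshold.

## Known limitations

* The generators draw daily weather independently across days; agreement
  indices on real (autocorrelated) series will differ in level, though the
  sunny/shaded orderings are driven by variance ratios that transfer.
* The Scheirer–Ray–Hare $\chi^2$ reference is asymptotic; at very small
  cell counts (≤3) its size can drift from nominal, as for any rank test.
* `chamber_radius()` reduces an elliptical base to one radius; all four
  reduction rules are approximations to an unmeasured geometry.
* The equal-proportions $\chi^2$ is reported in both uncorrected and
  Yates-corrected forms; published values computed from unavailable raw
  denominators may match neither, and the package deliberately does not
  tune toward any printed statistic.
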