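---
title: "Methods: from radiocarbon databases to rapid-climate-change matching"
author: "holodem"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holodem)
```

`holodem` implements a quantitative chain that links archaeological
radiocarbon-date databases to paleoclimate proxy series: probabilistic
calibration, summed probability distributions (SPDs) read as a relative
population signal, occupation-gap and antiphase detection, nonparametric
regional comparison, a coefficient-of-variation detector for epochs of
extreme climatic variability in speleothem isotope records, interval
matching of demographic gaps against a catalogue of rapid climate change
(RCC) events, and a shelf-inclination model of coastal territorial loss.
This vignette records the models, the conventions, and the design choices
where the design was genuinely open.

## Calibration model

A radiocarbon determination is a measured age $y$ (¹⁴C yr BP) with
laboratory error $\sigma_y$. A calibration curve supplies, for each
calendar age $\theta$ (cal BP, years before AD 1950, increasing into the
past), the expected radiocarbon age $\mu(\theta)$ and curve error
$\sigma_c(\theta)$; between knots both are linearly interpolated (linear
interpolation is standard, monotone between monotone knots, and exactly
reproducible; no spline is used). The calibrated density on a regular
calendar grid is

$$p(\theta) \propto
  \phi\!\left(\frac{y - \mu(\theta)}
  {\sqrt{\sigma_y^2 + \sigma_c(\theta)^2}}\right),$$

normalized to unit mass per date. Numerical choices:

* **Grid step 5 yr** by default (configurable). Sub-decadal precision
  exceeds what the data support, and the step keeps densities compact.
* **Truncation at 5 combined standard deviations**: cells with
  $|y-\mu(\theta)| > 5\sqrt{\sigma_y^2+\sigma_c^2}$ carry numerically
  negligible mass and are dropped before normalization.
* **Support clipping is an error, not a warning.** If more than $10^{-3}$
  of the untruncated Gaussian mass falls beyond the ends of the curve
  (estimated from the endpoint likelihoods), calibration aborts: a
  silently renormalized clipped density would bias every downstream
  statistic.
* **Point estimate = median**, defined as the smallest grid age whose
  cumulative mass *strictly exceeds* one half (a cell that brings the
  cumulative total to exactly 0.5 leaves the median at the next cell).
  The median is stable under grid refinement, unlike the mode of a
  multimodal density. The 95% interval is the outer envelope of the
  highest-density set of cells covering at least 0.95 mass.
* Each date is normalized individually; no curve-prior reweighting is
  applied.

On a linear curve of slope $a$ with zero curve error these conventions
give back the Gaussian limit: median $(y-b)/a$ within one grid step and
standard deviation $\sigma_y/|a|$ within 2%, which the test suite checks.

## SPDs, gaps, and antiphasing

The SPD of a date set is the cell-wise sum of the per-date densities.
Unnormalized, its total mass equals the number of dates (the additive
"archaeological signal" convention); `normalize = TRUE` divides by that
count. No per-site pre-aggregation is applied before summation — the
analyses this package reproduces describe none — though dates can be
filtered by region before summation.

A **gap** is a maximal run of cells with density below
`rel_threshold` × (mean cell density over the analysis window), lasting
at least `min_duration` years. Defaults: threshold fraction 0.05, minimum
duration 200 yr, window 15,000–0 cal BP (records older than 15 ka are
sparse enough that SPD depletion stops being interpretable as
demography). One rule is ours: a below-threshold run touching either edge
of the analysis window is *not* reported. At the edges of a record the
SPD decays through its constituent densities' tails, so every SPD ends in
low-density runs; these are censoring of the record, not gaps bracketed
by occupation, and treating them as gaps would plant artifacts at every
record end.

**Antiphasing** between two regions is scored by resampling both SPDs
onto a common grid over a window (at least 1000 yr, contained in both
records) and taking the Spearman rank correlation of the density vectors.
Scores ≤ −0.3 are labelled "antiphased", ≥ 0.3 "in-phase", otherwise
"indeterminate". The ±0.3 cut-offs and the 1 ka minimum window are
descriptive conventions of this package, not significance claims.

## Nonparametric comparisons

Regional date sets are compared on **per-date calibrated medians** — the
only per-date scalar the workflow produces — using:

* `mann_whitney()`: $U$ counts pairs with $x > y$, ties as ½. The
  two-sided p is exact (null permutation distribution of $U$) when
  $\min(n_1,n_2) \le 8$ with no ties, otherwise a tie-corrected normal
  approximation without continuity correction; the `method` field records
  the branch. The test suite verifies the exact branch against brute-force
  enumeration of all $\binom{n_1+n_2}{n_1}$ labelings.
* `kruskal_wallis()`: tie-corrected $H$ with a $\chi^2_{k-1}$ p-value,
  delegated to `stats::kruskal.test()`.
* `spearman_rank()`: Pearson correlation of mid-ranks with the
  $t_{n-2}$ approximation for p. The $t$ convention is fixed so that
  results are identical across sample sizes (rather than switching
  between exact, Edgeworth and asymptotic formulas).

## The variability detector

For an age-ordered proxy series (e.g. speleothem δ¹⁸O), every adjacent
pair $(x_1, x_2)$ yields a coefficient of variation

$$\mathrm{CV} = \frac{|x_1 - x_2|/\sqrt{2}}{|(x_1+x_2)/2|},$$

dated to the midpoint of the two sample ages. The numerator is the
two-point *sample* standard deviation ($n-1$ convention); the population
convention ($|x_1-x_2|/2$) is available by flag and differs only by a
uniform $\sqrt 2$, to which the epoch flagging below is invariant. The
absolute mean makes uniformly negative series (typical δ¹⁸O) yield
positive CVs; a pair whose mean is zero has no defined CV and raises an
error rather than returning an unstable value.

Pairwise CVs are averaged in fixed bins of width $w$ (250 yr for the
quarter-millennium analyses, 120 yr for high-resolution records),
anchored at 0 cal BP. The extreme-variability threshold is
$\tau = \bar m + \bar s$: mean plus one standard deviation, computed by
default over the nonempty bin means, optionally over the raw pairwise CVs
(`stats_on = "raw"`) — published figures exist in both conventions, so
both are supported. A bin is flagged when its mean CV strictly exceeds
$\tau$. Empty bins are reported as missing, never as zero. Note that a
mean-plus-one-sd cutoff flags roughly the upper sixth of a stationary
series by construction; the detector is informative through the
*contrast* between epochs, not through its false-flag rate in isolation.

Growth rates are depth increments over age increments per adjacent pair
(mm/yr); a depositional **hiatus** is an adjacent age gap exceeding
`max(abs_min, rel_factor × median spacing)` (defaults 500 yr and 10),
which never fires on uniformly spaced records for any factor above 1.

## RCC catalogue and matching

The bundled catalogue (`inst/extdata/rcc_events.csv`) holds 28 published
rapid-climate-change events as labelled calendar intervals in ka BP, from
Meltwater pulse 1A (14.9–13.9 ka) to the Little Ice Age (0.75–0.1 ka);
point events ("ca. X ka") are stored with equal bounds. An event matches
a demographic interval when its range, widened by the tolerance (default
0.1 ka) on both sides, intersects the interval; intervals are closed, so
touching counts. All matches are reported, sorted by overlap length —
the catalogue contains overlapping event families and no precedence among
them is assumed. The verdict is "yes" or "no"; "unclear" is a user
annotation, not a matcher output. Widening the tolerance can only add
matches, and verdicts are invariant to working in ka or cal BP.

## Coastal shelf model

For a planar submerged shelf of average inclination $\theta$ between
present sea level and the −100 m isopleth, a unit rise of sea level
submerges a strip of surface length $\csc\theta$. The relative loss of a
shelf against a reference is $100(\csc\theta_1/\csc\theta_2 - 1)$,
rounded to the nearest integer percent. The cosecant form was chosen
because it reproduces both published profile comparisons (25° vs 70° →
122%; 45° vs 70° → 33, printed as 32 under truncation), while a
horizontal-retreat model $1/\tan\theta$ reproduces neither; the printed
inclinations are steep for real shelf slopes and are treated as given
inputs, not re-derived from bathymetry.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with truth
sidecars so detectors can be scored:

* `sim_curve()`: a monotone calibration curve
  $\mu(\theta)=\theta+w(\theta)$ with a smooth three-sinusoid
  perturbation of bounded amplitude; amplitudes that would break
  monotonicity are damped with a warning. Wiggles are smooth seeded
  perturbations, not the plateau-and-reversal structure of the real
  IntCal record; analyses requiring the published curve must load it
  explicitly via `load_curve(..., "intcal")`.
* `sim_dates()`: calendar ages drawn from piecewise-constant occupation
  intensities, mapped through $\mu$, perturbed by Gaussian lab error
  (drawn once per date; no inter-laboratory offsets, no taphonomic loss,
  no research bias — all of which shape real databases).
* `sim_isotope()`: AR(1) residuals (marginal sd = base sd × epoch
  multiplier, lag-1 correlation ρ) on irregular ages. Real speleothem
  records add age-model uncertainty and secular trends not modelled here.
* `sim_depth_age()`: piecewise-constant deposition with hiatuses; depth
  integrates rate from the top.

Passing the recovery tests therefore shows that the detectors recover
the signals they are designed for *under the generating assumptions*
(piecewise-constant intensity, variance-regime AR(1) noise); it does not
certify performance against sampling bias, age-model error, or reservoir
effects in real data.

## Study conditions and problem sizes

The recovery properties are evaluated at the scale the analyses target:
gap recovery uses 200 dates per replicate with occupation on
8000–6500 and 4500–2000 cal BP and none in between (lab error 30 ¹⁴C yr,
wiggly curve, 100 seeded replicates; success = exactly one gap within
±250 yr of truth, required in ≥ 95% of replicates). Epoch recovery uses
an 11,000-yr series, baseline sd 0.15‰ at mean level −5‰, ρ = 0.5,
~20-yr sampling, one 1000-yr epoch at 4× sd, 250-yr bins (≥ 75% of epoch
bins flagged and ≤ 10% false flags outside, in ≥ 90% of 100 replicates).
These sizes match the density of the motivating datasets (sub-decadal to
multidecadal speleothem sampling; hundreds of dates per region).

## Known limitations

* No Monte-Carlo null envelopes for SPDs, no taphonomic or
  sampling-bias correction, no Bayesian sequence modelling, no marine
  reservoir handling — out of scope by design.
* The gap rule is threshold-based and shares the usual sensitivity of
  such rules near the threshold; bounds are honest only to about one
  grid step plus the calibration smearing of the constituent dates.
* Rank tests on calibrated medians discard within-date calendar
  uncertainty.
* The matcher reports *temporal coincidence* with catalogued events,
  which is necessary but never sufficient for causal attribution.
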