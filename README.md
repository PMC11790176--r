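# holodem

Tools for reading archaeological radiocarbon-date databases as a
*population proxy* and confronting them with paleoclimate proxy series.
The intended users are archaeologists and paleoclimatologists working on
Holocene demography — in particular on the question of whether regional
depopulation episodes line up with rapid climate change (RCC) events
rather than with long wet/dry phases.

The package covers the full chain:

1. **Calibration** — a determination $y \pm \sigma_y$ (¹⁴C yr BP) becomes a
   calendar-age density
   $p(\theta) \propto \phi\big((y-\mu(\theta))/\sqrt{\sigma_y^2+\sigma_c(\theta)^2}\big)$
   on a regular cal BP grid, where $\mu, \sigma_c$ come from a calibration
   curve (IntCal `.14c` dialect or plain CSV), normalized per date.
2. **SPDs** — summed probability distributions: cell-wise sums of the
   per-date densities, the standard relative "archaeological signal".
3. **Gaps and antiphasing** — maximal low-density runs below a fraction of
   the window mean (default 5%, ≥ 200 yr), and Spearman rank correlation
   of two regional SPDs on a common grid (≤ −0.3 labelled antiphased).
4. **Regional comparison** — Mann-Whitney U (exact for small tie-free
   samples), Kruskal-Wallis H, Spearman correlation, on per-date
   calibrated medians.
5. **Variability detection** — adjacent-pair coefficients of variation of
   speleothem δ¹⁸O/δ¹³C series, $\mathrm{CV} = (|\Delta x|/\sqrt2)/|\bar x|$,
   binned in fixed time slots; bins whose mean CV exceeds the series mean
   plus one standard deviation are flagged as epochs of extreme
   variability. Growth rates and depositional hiatuses from depth-age
   columns.
6. **RCC matching** — a bundled 28-event catalogue of rapid climate change
   intervals (Meltwater pulse 1A through the Little Ice Age); demographic
   gaps and flagged epochs are matched by interval intersection with a
   ±0.1 ka tolerance and tabulated region by region.
7. **Coastal model** — territorial loss per unit sea-level rise on a shelf
   of inclination θ scales as csc θ.
8. **Synthetic data** — seeded generators for wiggly monotone calibration
   curves, occupation-driven date sets, variance-regime AR(1) isotope
   series and depth-age records with hiatuses, each with a truth sidecar,
   so the whole pipeline is testable offline.

## Worked example

Simulate a region occupied 9000–6500 and 4500–2000 cal BP with nothing in
between, rebuild its SPD, detect the gap, and match it against the RCC
catalogue:

```r
library(holodem)

curve <- sim_curve(c(0, 12000), wiggle_amp = 40, wiggle_period = 600, seed = 61)
occ   <- data.frame(start = c(9000, 4500), end = c(6500, 2000),
                    intensity = c(1, 1))
sim   <- sim_dates(occ, 200, curve, lab_sd = 30, seed = 62)

spd <- build_spd(sim$dates, curve)
spd
#> SPD 'all': 200 dates, 1775-9135 cal BP at 5 yr step

(gaps <- detect_gaps(spd))
#>   start  end duration mean_density_inside threshold_used
#> 1  6450 4550     1900        7.169165e-05    0.006788866

reports <- match_intervals(gaps, load_rcc_catalog(), tolerance = 0.1,
                           region = "Synthetic A")
build_region_table(reports)
#>   area_region instability_age_ka          evidence
#> 1 Synthetic A         6.5 to 4.5 Age SPD depletion
#>                                                            rcc_relation
#> 1 Yes - 5.5 ka event + 5.3 ka event + 4.8 warm excursion + 6.4 ka event
```

The planted 6500–4500 cal BP hiatus comes back within one grid step
(6450–4550: the bounds shrink by the calibration smearing of the edge
dates), and the matcher lists every catalogued event whose interval —
widened by the 0.1 ka tolerance — intersects it, sorted by overlap.

Single-date calibration and the other stages work the same way:

```r
calibrate_date(5630, 35, curve)
#> Calibrated density for 5630 +/- 35 14C BP: median 5660 cal BP, 95% [5575, 5720]
mann_whitney(c(1, 2), c(3, 4))
#> U = 0.0000 (n = 2, 2), p = 0.3333 [exact]
loss_increase_pct(25, 70)
#> [1] 122
```

(The median above is against the *synthetic* curve; against IntCal20 the
same determination calibrates to about 6.4 ka cal BP.)

`run_pipeline()` orchestrates everything from a config list or YAML file
(curve + dates CSV + optional isotope CSVs in, per-region SPD/gap/test/CV
outputs and an RCC match table out, each output stamped with the
configuration hash).

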