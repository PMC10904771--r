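# axoflux

Analysis of how slowed voltage-gated Na⁺-channel (Na_v) inactivation —
the hallmark effect of scorpion alpha-toxins — reshapes action-potential
(AP) generation in the axon initial segment (AIS), quantified from
voltage-clamp currents, electrode recordings and high-speed fluorescence
imaging. The package is written for electrophysiologists and imaging labs
who need the full measurement chain (preprocessing → model fitting →
metrics → paired statistics) as reusable, tested code, together with a
biophysical simulator that generates synthetic cohorts with a known ground
truth for validating every step.

## What it computes

**Voltage-clamp dose–response.** For a step from −100 mV to 0 mV (50 ms,
20 kHz), the half-inactivation time

> T50 = time from the current peak to the half-way point of the
> peak-to-residual decay (linearly interpolated),

per-cell relative T50 increases, and per-concentration tables normalised
so the maximal mean increase is 1. Toxin binding is an equilibrium Hill
model: occupancy φ(c) = cⁿ/(cⁿ + EC₅₀ⁿ); bound channels inactivate
`slowdown`-fold more slowly and keep a `persistent_frac` floor of their
conductance.

**AP shape metrics.** Amplitude (baseline to peak) and width *Wid* (total
time with V_m > −30 mV, interpolated crossings, multiple intervals
summed), on electrode traces and on optical AP waveforms normalised
baseline-to-peak against the somatic AP.

**Indicator transients.** ΔF/F₀ extraction with multi-exponential
photobleaching correction; Na⁺ transients fitted with a sum of logistic
sigmoids, Ca²⁺ transients with a 4-sigmoid product; ionic currents
estimated as the **analytic time-derivative of the fits** (for one
logistic component the current peaks at exactly a/4τ).

**Cohort statistics.** Percent changes per cell, paired t-tests with
significance at p < 0.01, and the regional proximal (5–15 µm) versus
distal (30–40 µm) Ca²⁺ decomposition.

**Synthetic data.** A soma-plus-axon Hodgkin–Huxley-style simulator
(5 µm compartments to 45 µm, toxin-partitioned Na⁺ conductance,
Na_v-mediated Ca²⁺ entry rising distally, VGCC entry falling distally)
plus a fluorescence forward model (gain, multi-exponential bleaching,
camera noise, 20/10 kHz frame rates, one master seed).

## Worked example

A control voltage-clamp current and its T50:

```r
library(axoflux)
tox <- toxin_model(ec50 = 0.3, hill_n = 1.5, slowdown = 3,
                   persistent_frac = 0.1)
tr <- simulate_vc_current(vc_protocol(), na_channel(), tox, conc = 0.3)
compute_t50(tr)
#> $t50
#> [1] 1.407863
#> $peak_time
#> [1] 0.55
#> $peak_value
#> [1] 0.7917577
#> $residual_value
#> [1] 0.06000003
```

At 0.3 nM (the EC50) half the channels are toxin-bound, and T50 has grown
from ~0.85 ms (control) to 1.41 ms: inactivation is markedly delayed, with
a 0.06 nA persistent current remaining at the end of the step.

A full 9-cell synthetic cohort, control versus 7 nM local toxin delivery:

```r
run <- run_pipeline(run_config(seed = 1, cohort_n = 9))
print(run$summary, digits = 3)
#>        metric n mean_change sd_change t_stat  p_value significant
#> 1     ais_wid 9      36.481     8.460  12.94 1.21e-06        TRUE
#> 2   ca_distal 9      21.829     0.594 110.32 5.09e-14        TRUE
#> 3     ca_peak 9       8.188     1.942  12.65 1.43e-06        TRUE
#> 4 ca_proximal 9       0.304     1.183   0.77 4.63e-01       FALSE
#> 5     na_peak 9      21.733     1.570  41.52 1.25e-10        TRUE
#> 6    soma_wid 9       8.389     0.331  76.08 9.93e-13        TRUE
```

Reading the table: the toxin widens the somatic AP by ~8% but the AIS AP
by ~36% (larger in the AIS in every one of the 9 cells); the Na⁺
peak-transient gain (~22%) exceeds the Ca²⁺ gain (~8%); and the Ca²⁺ gain
is confined to the distal AIS (~22%, significant) while the proximal AIS
is flat (0.3%, not significant) — the signature of Ca²⁺ entry through
Ca²⁺-permeable Na_v channels rather than through voltage-gated Ca²⁺
channels.

```r
print(run$tests$ais_wid)
#> Paired t-test: n = 9, mean change = 36.5 +/- 8.46 (SD), t = 12.9,
#>   p = 1.21e-06 (significant at 0.01)
```

`make_report(run)` renders the figure-level panels (paired width scatter,
per-metric change plots, dose curve), and `write_run_bundle()` emits tidy
CSV tables with a reproducibility manifest. A thin command-line wrapper
lives at `inst/cli/axoflux.R`:

```sh
Rscript inst/cli/axoflux.R run --seed 1 --out results/
```

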