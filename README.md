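# chainelong

Stoichiometric analysis and simulation of ethanol-based chain-elongation
bioreactors steered by CO2 dosing.

## The problem

Open-culture ("reactor microbiome") chain elongation converts short-chain
carboxylates (acetate, n-butyrate) and an electron donor (ethanol) into
medium-chain carboxylates — chiefly n-caproate — and, under the right
conditions, their corresponding alcohols (butanol, hexanol). The CO2 supply
rate is a powerful steering handle: it feeds chain-elongator anabolism, but
in excess it enriches homoacetogens that burn ethanol and H2 into acetate.
Judging what a reactor is actually doing therefore hinges on careful
stoichiometric bookkeeping of noisy, rarely-steady time series.

`chainelong` turns raw reactor check-up data (broth concentrations, feed
and base flows, gas dosing, off-gas composition) into that bookkeeping, for
the bioprocess engineers and fermentation scientists who run such reactors:

* **Volumetric conversion rates** per compound and measurement interval in
  mCmol L⁻¹ d⁻¹, for a constant-volume overflow CSTR with accumulation
  correction: `r_i = (C_i·Q_out − C_feed,i·Q_feed)/V + dC_i/dt`.
* **Cmol% product selectivity**: carbon in each formed product over the
  carbon in all formed products.
* **Carbon and electron balance closure** (degree-of-reduction weighting,
  γ = (4n_C + n_H − 2n_O − 3n_N)/n_C; H2 = 2 e⁻ eq mol⁻¹), including
  gaseous CO2/H2/CH4 and CO2 dissolved in the effluent
  (Henry + bicarbonate speciation).
* **Excessive ethanol oxidation (EEO)**: assuming one ethanol is oxidised
  to acetate per five elongation events,
  `EEO% = 100·(E_cons − S − E_red − S/5)/E_cons`, with elongation steps S
  inferred from net product rates and E_red the ethanol spent on
  carboxyl–hydroxyl exchange (one per mol higher alcohol formed).
* **Steady-state gating** (CV-over-window criterion), hydraulic retention
  times, end-of-phase averaging, and CSV/JSON report bundles.

Because such claims are untestable without ground truth, the package ships
a **stoichiometric CSTR simulator**: prescribed reaction-rate profiles
(chain elongation, ethanol oxidation, homoacetogenesis, carboxylate
reduction, isomerisation) drive exact liquid/gas balances and a realistic
measurement schedule, so every metric above can be verified by parameter
recovery against a known truth.

## Worked example

Simulate the four-phase CO2-dosing experiment (0 / 2.0 / 6.0 / 0.5
NmL L⁻¹ min⁻¹ over 133 days, medium 600 mMC butyrate + 50 mMC acetate +
1200 mMC ethanol) with the default measurement model, then analyse it:

```r
library(chainelong)
sim     <- simulate_preset("experiment", seed = 42)
metrics <- reactor_metrics(sim$timeseries, feed_definition(), n_last = 5)
summary(metrics)
```

```
Chain-elongation metrics for reactor 'experiment'
  57 intervals; mean carbon balance 100.2%, electron balance 100.1%
  phase summary (end-of-phase windows):
 phase n_used hrt_h carbon_balance_pct electron_balance_pct eeo_pct
     I      5 41.99             100.58               100.62 -25.640
    II      5 41.80             100.33               100.38   7.530
   III      5 43.38              98.93                98.92  54.319
    IV      5 43.38              99.37                99.33   4.037
 co2_utilization_mCmol_L_d
                   0.00000
                   6.04768
                  28.58490
                   0.09067
  phase product selectivities (Cmol%):
    acetate i-butyrate n-caproate butanol hexanol
I       0.0        0.0       98.8     0.2     1.0
II     12.1        0.0       82.9     1.4     3.6
III    39.6        2.9       54.7     0.0     2.8
IV      7.5        0.0       86.8     2.3     3.4
```

Reading the table: without CO2 (phase I) the reactor elongates almost
exclusively to caproate (98.8 Cmol%) and the EEO is strongly negative —
less ancillary ethanol oxidation than the assumed 5:1 stoichiometry. CO2
overloading (phase III) flips the spectrum toward acetate with EEO ≈ 54%,
and trimming CO2 back (phase IV) restores selective caproate formation
with a maintained butanol+hexanol side stream (≈ 5.7 Cmol%) and EEO near
zero. Balances hover around 100% because the simulated chemistry conserves
carbon and electrons exactly; the residual percent-level scatter is the
measurement noise. The underlying ground truth for each phase is in
`sim$truth$phase_metrics`.

The same analysis runs from a YAML configuration:

```r
run_pipeline(list(preset = "experiment", seed = 42, out_dir = "out"))
# or: run_pipeline("config.yaml")
```

which writes `timeseries.csv`, `rates.csv`, `metrics_interval.csv`,
`phase_summary.csv/.json`, `ground_truth.json` and `pipeline.log` into
`out/`. Measured data enter through `read_timeseries()` (tidy CSV:
`time, variable, species, value, unit`; units converted through the
shipped compound registry).

## Limitations

The simulator prescribes reaction extents rather than growing them from
microbial kinetics, treats the headspace as quasi-steady and gas–liquid
CO2 exchange as equilibrium, and does not model pH dynamics, biofilm
structure or community composition. See the methods vignette
(`vignettes/chain-elongation-stoichiometry.Rmd`) for the full model
description, parameter defaults and design rationale.
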