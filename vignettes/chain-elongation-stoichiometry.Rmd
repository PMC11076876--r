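---
title: "Stoichiometric accounting for CO2-steered chain-elongation reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric accounting for CO2-steered chain-elongation reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainelong)
```

## Scope and model

`chainelong` analyses continuous ethanol/carboxylate chain-elongation
reactors — retentostats fed with a butyrate/acetate/ethanol medium and
steered by CO2 dosing — as constant-volume overflow CSTRs. The package
answers three questions from routine check-up data: *how fast is each
compound converted*, *where do carbon and electrons go*, and *how much
ethanol is oxidised beyond what chain elongation itself requires*.

Three assumptions define the accounting model:

1. **Constant working volume**: the effluent flow equals feed plus base
   flow (`Q_out = Q_feed + Q_base`), and the base stream carries no
   carbon. Base dosing for pH control therefore shortens the hydraulic
   retention time, `HRT = V / (Q_feed + Q_base)`.
2. **Accumulation matters**: these reactors are rarely at steady state, so
   the per-interval conversion rate includes the `dC/dt` term,
   `r_i = (C_i Q_out − C_feed,i Q_feed)/V + ΔC_i/Δt`,
   attached to the interval's right endpoint. A flag
   (`accumulation = FALSE`) yields the pure flow-through estimate for
   comparison.
3. **Charge-free elemental bookkeeping**: acids are balanced in their
   undissociated form and concentrations are carried in mCmol/L (the mMC
   convention), so carbon balances need no speciation. pH enters only
   through base-flow bookkeeping and the dissolved-CO2 model.

### Units and the electron scale

All broth chemistry runs in mCmol L⁻¹ (d⁻¹); gas dosing in NmL per L
reactor per min. "Normal" gas conditions are nowhere standardised, so the
package defaults to 273.15 K / 101.325 kPa (22.414 NmL/mmol) and exposes
`molar_volume` everywhere a different convention might apply.

Electron balances use one documented unit: *available electron
equivalents* per mol, `γ·n_C` with
`γ = (4 n_C + n_H − 2 n_O − 3 n_N)/n_C` (CO2/H2O/NH3 reference). On this
scale H2 carries 2 equivalents per mol and O2 −4; CO2, H2O, N2 and NH3
carry none. The anchor identity is hydrogenogenic ethanol oxidation,
`EtOH + H2O → acetate + 2 H2` (12 = 8 + 4), which the test suite asserts
together with the closure of every shipped reaction. The generic biomass
formula CH1.8O0.5N0.2 (γ = 4.2) is available but excluded from balances
by default, since reactor carbon accounting in this field usually leaves
biomass untracked.

### Gas-phase CO2 accounting

CO2 utilisation is the difference between dosed CO2 and outgoing CO2,
where "outgoing" sums the off-gas term (flow × headspace mole fraction)
and the carbon dissolved in the effluent. Dissolved inorganic carbon
assumes gas–liquid equilibrium with the measured headspace partial
pressure: `DIC = K_H · pCO2 · (1 + 10^(pH − pKa1))`, with defaults
`K_H = 0.026 mol L⁻¹ atm⁻¹` and `pKa1 = 6.31` appropriate for 35 °C.
Whether published dissolved-CO2 figures include bicarbonate is often
unstated, so `speciation = FALSE` switches to free CO2(aq) only; both
constants are configurable. The identity
`utilisation = in − out_gas − out_dissolved` holds by construction and is
tested as such.

## Excessive ethanol oxidation

Chain elongators are assumed to oxidise one ethanol to acetate per five
elongation events. Everything beyond that — and beyond elongation itself
and carboxylate reduction — is *excess*:

```
EEO% = 100 · (E_cons − S − E_red − S/5) / E_cons        (mol ethanol)
```

`S`, the number of 2-carbon elongation events, is not directly observable
and must be inferred from net product rates. The package's default rule:

* one step per net mol butyrate formed (C2→C4), one per C6→C8;
* caproate (plus hexanol) formation is fed by net-consumed butyrate
  first (1 step each); any remainder is attributed to acetate (2 steps);
* alcohols count as their precursor acid for step accounting, and each
  mol of higher alcohol assigns one extra ethanol to carboxyl–hydroxyl
  exchange (`E_red`), crediting one acetate;
* isobutyrate counts as an isomerisation (0 steps) by default;
  `isomer_steps = 1` treats it as an elongation event;
* valerate counts one step (elongated propionate).

Because published EEO definitions defer to earlier work whose step
accounting may differ, the isomer rule and the step inference are exposed
as options rather than hard-coded. A useful property of the net-routing
rule: for the shipped reaction network it reconstructs
`S = r_CE1 + r_CE2` exactly from net rates alone, because internal C4
cycling (produced by CE1, consumed by CE2) cancels in the routing
arithmetic. Negative EEO values are reported as-is; they mean the culture
elongates with less ancillary oxidation than the 5:1 assumption.

### Sampling error of the EEO estimator

EEO is a ratio of differences of large, noisy terms. With ethanol fed in
roughly sevenfold excess over its consumption, a per-sample concentration
CV of ε inflates to ~7ε on the consumption estimate. Under the default
measurement model (3% GC error per replicate, duplicate analyses, three
samplings per week) error propagation puts the phase-level EEO standard
deviation near 2.4 percentage points even when rates are averaged over a
full 16-interval steady window — which is why phase-level EEO should
always be read with that uncertainty in mind, and why the package computes
phase metrics from *window-averaged rates* rather than averaging
per-interval ratios. Selectivities, by contrast, are ratios of large
positive quantities and recover to a fraction of a Cmol point under the
same noise.

## Steady-state gating and phase averaging

Steadiness is declared per trailing window: at least three samples
spanning `window_span` (default 3) HRTs in which every tracked compound's
coefficient of variation is at most `max_cv` (default 0.10). The criterion
is scale-invariant and monotone in `max_cv` (tightening can only shrink
the steady set); both properties are tested. The defaults are a
documented choice, not a community standard — published steady-state
rules for these reactors live in cited prior work and vary — so the
criteria object is fully configurable.

Phase-level reporting follows the end-of-phase convention: the mean of
the last `n_last` (default 5) interval records before the next set-point
change, with selectivity denominators built from those averaged rates.
Phase intervals are half-open `[start, end)`: a sample taken on the day a
set-point changes belongs to the new phase, matching how dosing
adjustments are logged.

## The simulator: what it emulates, and what it does not

The generator mimics the study conditions of a two-retentostat,
four-phase CO2-dosing campaign: 1 L working volume, 522 mL/d feed, medium
of 600 mMC butyrate + 50 mMC acetate + 1200 mMC ethanol (+ 1 g/L
untracked yeast extract), phases of 0 / 2.0 / 6.0 / 0.5 NmL CO2 L⁻¹ min⁻¹
with 6 NmL N2 L⁻¹ min⁻¹ from phase III on (days 34/57/91/133), KOH
molarity switched from 1 M to 2 M on day 55, sampling three times a week,
and duplicate GC analyses with 3% error per replicate.

Design choices, in decreasing order of consequence:

* **Prescribed rate profiles.** Reaction rates are inputs (constant per
  phase, or logistic ingrowth for slowly establishing acetogenic
  activity), not outputs of a growth model. No growth kinetics are
  available to calibrate, and prescribing extents keeps the ground truth
  exact — the whole point of the generator is parameter recovery.
* **Quasi-steady headspace.** Off-gas composition equals the
  instantaneous source mix; the gas residence time is minutes against a
  sampling cadence of days. CO2-consuming reactions are capped at their
  supply, and hitting the cap raises an `underpressure` flag (the
  laboratory failure mode it mimics is a collapsing water lock).
* **Consistent dissolved CO2.** The simulator splits outgoing CO2 between
  off-gas and effluent with the same equilibrium model the analysis uses,
  solving the resulting fixed point in closed form (a quadratic). This is
  what lets carbon balances close at exactly 100% through the pipeline.
* **Base dosing** is proportional to net acid formation (configurable
  gain, default full neutralisation); H2 is treated as insoluble in the
  liquid balance.

Presets `phaseI`, `phaseII`, `phaseIII_R2` and `phaseIV` encode the four
regimes; `experiment` strings them together. Preset elongation and
reduction rates were fixed once from the printed phase-IV performance
(caproate ≈ 299, butanol 7.6, hexanol 11.7 mCmol L⁻¹ d⁻¹) and the
qualitative phase patterns; each preset's ethanol-oxidation rate is then
*derived algebraically* from its target excess fraction
(`E_cons = (S + E_red + S/5)/(1 − f)`), so the configured f ∈
{0, 0.1, 0.5} is the exact ground truth the recovery tests check against.

What the generator does **not** emulate: microbial community dynamics and
their feedback on rates, biofilm/suspension compartmentalisation, pH
excursions and the accidental batch episodes of real campaigns,
gas–liquid transfer limitation, and analytical artefacts beyond
multiplicative noise (drift, carry-over, detection limits). Passing
recovery tests therefore demonstrates that the *accounting* is correct
and robust to measurement noise — not that real reactors obey prescribed
stoichiometry.

## Numerical choices

* ODE integration: `deSolve::lsoda`, `rtol 1e-10`, `atol 1e-8`,
  restarted at phase boundaries so rate discontinuities never cross an
  integrator step. The no-reaction wash-in curve reproduces the
  closed-form CSTR response to ~1e-10 relative.
* Interval averaging: rate estimates use midpoint (trapezoid) means of
  concentrations and flows by default — second-order accurate, and exact
  at steady state; `method = "endpoint"` reproduces the cruder
  right-endpoint convention.
* Ground-truth interval rates integrate the effective (capped) rate
  profiles by composite open-midpoint quadrature between discontinuities,
  exact for piecewise-constant schedules.
* Degenerate inputs: HRT is undefined (error) at zero total flow; EEO is
  `NA` with a warning when ethanol is not net consumed; selectivity of an
  all-negative rate vector is an empty result with a warning; a CV over
  an identically-zero tracked compound counts as steady; negative
  concentrations during integration abort with the offending species and
  day (infeasible rate profile).
* Problem sizes: the shipped tests and acceptance script use 20–60-sample
  simulations (40–133 days at 2–3-day spacing, daily for rate-recovery
  checks); the whole suite runs in well under a minute.

## Known limitations

Step inference from net rates is exact only when product routing matches
the actual pathway hierarchy; exotic networks (e.g. substantial C8 from
C2, concurrent odd-chain elongation) would need a custom step rule, which
is why the rule is an option. The dissolved-CO2 model ignores carbonate
(negligible below pH 8) and mass-transfer kinetics. The EEO statistic
inherits the 5:1 ATP assumption; the package reports the allocation
terms (`elongation`, `expected_oxidation`, `reduction_exchange`,
`excess`) alongside the percentage so that assumption can be revisited.
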