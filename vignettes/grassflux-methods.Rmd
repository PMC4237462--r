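---
title: "Methods: water balance, leaf energy balance and seasonal inference in grassflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water balance, leaf energy balance and seasonal inference in grassflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grassflux implements the computational chain of a common-garden drought
experiment comparing C3 and C4 grasses: micrometeorological water-deficit
accounting, biophysical estimation of leaf transpiration, quality control
and derivation of water-use quantities from chamber gas exchange, plant
hydraulic indices from paired water potentials, and a mixed-model
inference layer with bootstrap intervals. Because such experiments rarely
deposit raw data, the package ships a seeded synthetic-field generator
that reproduces the statistical structure the analysis assumes, so the
entire chain is testable end to end. This vignette documents the models,
the defaults, the numerical choices, and what the synthetic tests do and
do not establish.

## Water balance

**Reference evapotranspiration.** Daily ET0 (mm day^-1^) uses the FAO-56
combination equation over a reference grass surface,

$$\mathrm{ET}_0 = \frac{0.408\,\Delta\,(R_n - G) + \gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}{\Delta + \gamma\,(1 + 0.34\,u_2)},$$

with soil heat flux $G = 0$ at the daily step. Daily mean temperature and
relative humidity are the mean of the daily maximum and minimum — the
convention of the field campaign this pipeline models — so $e_s$ is
evaluated at $T_\text{mean}$ rather than averaged over the extremes.
Saturation vapour pressure uses the Tetens exponential; the psychrometric
constant comes from standard-atmosphere pressure at the site altitude
(642 m default).

**Radiation from PPFD.** The weather station logs photon flux only.
Global shortwave is recovered as $R_s = \mathrm{PPFD}/2.1$ W m^-2^
(2.1 umol J^-1^ of PAR, PAR = 0.5 of global); this single conversion
feeds both ET0 and the leaf model. Net radiation follows FAO-56: albedo
0.23, and net longwave from the Stefan–Boltzmann law with the
$0.34 - 0.14\sqrt{e_a}$ humidity correction and a clear-sky fraction
estimated against extraterrestrial radiation for the site latitude and
day of year. These are the natural defaults where the station metadata
is silent; the conversion is a documented utility
(`ppfd_to_shortwave()`), not a buried constant. Rare negative outputs of
the combination equation (cold, wet, still days) are clamped to zero and
flagged.

**Watering policy.** The experiment adds 28 L per 2 m x 2 m plot
(7 mm) on an alternating 2-/3-day cycle, and halts watering for 14 days
whenever rainfall exceeds 10 mm in any 48-h window. `watering_policy()`
implements the cycle as a fixed schedule from the season start; a halt
suppresses scheduled events but does not shift the cycle. Weekly
deficits are ET0 − (rain + irrigation) summed over consecutive 7-day
windows from the season start (not ISO weeks), with an exact telescoping
cumulative series. No soil bucket, runoff or drainage is modelled: the
deficit is a demand-side index, as in the source experiment.

**Treatment comparison.** `compare_weekly_deficits()` runs a two-sided
Wilcoxon signed-rank test on paired weekly deficits via
`stats::wilcox.test`, dropping zero differences (Wilcoxon's original
treatment — weeks inside watering halts produce exact zeros), exact for
up to 25 non-zero pairs and normal-approximated with continuity
correction above. All-zero difference series return p = 1 rather than an
error, since identical series carry no evidence. The test suite checks
the implementation against full enumeration of all $2^n$ sign
assignments for n up to 12.

## Leaf energy balance

Transpiration is not measured; it is estimated for a horizontal leaf
suspended over a lawn from stomatal conductance, leaf width and midday
microclimate. The converged state satisfies

$$R_\text{abs} = L_\text{out} + H + \lambda E,$$

with absorbed radiation $R_\text{abs}$ = 0.5 of global shortwave plus
longwave from a clear sky above (Brutsaert emissivity from vapour
pressure) and a lawn at air temperature below (emissivity 0.97);
$L_\text{out} = 2\,\varepsilon\,\sigma\,T_\text{leaf}^4$ from both
faces; sensible heat $H = c_p\,g_{bH}\,(T_\text{leaf}-T_\text{air})$
with the two-sided boundary-layer conductance; and
$E = g_{tv}\,(e_s(T_\text{leaf}) - e_a)/P$.

**Conductances.** The flat-plate forced-convection relation gives
$g_{bH} = 0.135\sqrt{u/d}$ mol m^-2^ s^-1^ per side, with a still-air
floor $u_\text{min} = 0.1$ m s^-1^. Stomatal conductance is taken as the
total reported by a gas-exchange system (already summed over surfaces,
the convention for narrow amphistomatous grass leaves) and acts in
series with the two-sided vapour boundary layer
($g_{bv} = 1.08\,g_{bH}$ per side).

**Numerics.** The closure residual is driven below 0.01 W m^-2^ by a
Newton iteration on leaf temperature with the analytic derivative
$-(8\varepsilon\sigma T^3 + c_p g_{bH} + \lambda g_{tv}\,s(T)/P)$ and a
5 °C step clamp. A fixed-point update damped by a constant factor is
the textbook alternative, but its iteration map has slope beyond −1 in
corners of the working envelope (calm air, wide leaves, high
conductance, warm air), where it cycles; Newton converges in 3–6
iterations everywhere in the documented box (air temperature 5–40 °C,
RH 10–95%, wind 0–10 m s^-1^, PPFD 0–2000 umol m^-2^ s^-1^, gs
0.01–0.5 mol m^-2^ s^-1^, width 1–20 mm) and the final state is
independent of initialization. Negative computed E (dew deposition) is
clamped to zero and flagged; dew formation is out of scope. A
linearized, closed-form Penman–Monteith solution
(`pm_transpiration_linearized()`) built on isothermal net radiation and
a radiative conductance serves as an internal cross-check: the two agree
within 5% whenever the leaf is within 2 °C of air temperature.

`estimate_monthly_E()` performs one solve per species x month x
treatment cell, pairing cell-mean stomatal conductance with the
campaign-window midday climate (daily maximum temperature, daily minimum
RH, mean wind, midday PPFD) and each species' leaf width.

## Gas-exchange quality control and water-use efficiency

Records are screened by independent, individually coded rules:
CO2 differential > 10 umol mol^-1^, H2O differential > 1 mmol mol^-1^,
projected leaf area >= 100 mm^2^, flow >= 100 umol s^-1^, ci
stabilization <= 180 s, and a per-month policy for tightly rolled
leaves. Leaf area is the mean of the combined leaf widths at the two
chamber edges times the 30 mm chamber length — the long axis of the
30 mm x 20 mm chamber, on the reading that narrow grass leaves span the
long axis; the edge mean is the minimal interpretation of widths
"at either edge" (a trapezoid rule would require positions that are not
recorded). Rolled-leaf handling mirrors the campaign's protocol change —
rolled leaves were unrolled only in the first month, and such records
are excluded thereafter — as a configurable month policy rather than
hard-coded dates. A record is kept iff no rule fails; every failure
contributes its own reason code, so filter counts decompose exactly by
rule.

Water-use efficiencies are simple ratios with unit bookkeeping:
intrinsic WUE $A/g_s$ in umol mol^-1^ and instantaneous WUE $A/E$ in
mmol mol^-1^ (umol CO2 per mmol H2O). Zero denominators make the ratio
undefined for that record (excluded from that variable); $A = 0$ yields
zero. Both are computed at the species x month x treatment level, the
unit at which E exists. Published seasonal tables sometimes print
$A/g_s$ in "mmol mol^-1^" at values three orders above what the units
imply; grassflux treats that as a labelling convention and keeps
dimensionally consistent umol mol^-1^.

## Hydraulics

Predawn and midday water potentials are paired per plant-month under the
field rules: predawn measured within 48 h of midday, and predawn values
with intervening rainfall discarded unless a repeat without rain exists.
Exclusions carry reason codes. The hydrodynamic gradient is
$\Delta\Psi = \Psi_\text{midday} - \Psi_\text{predawn}$ — negative
under daytime transpiration. The literature also writes the same
quantity as a positive drawdown $\Psi_\text{predawn} -
\Psi_\text{midday}$; the negative convention is the default here because
seasonal means are conventionally printed as negative values and makes
$K_\text{plant} = E/(-\Delta\Psi)$ positive, and the drawdown convention
is available via a flag rather than silently reconciled. Predawn
potential is treated as equilibrated soil potential; no disequilibrium
correction is applied. $K_\text{plant}$ uses the modelled monthly E
matched on species x month x treatment; zero gradients (DIV0) and
positive gradients (REVERSE_GRADIENT) are excluded with codes.

## Seasonal inference

The modelling unit is the species mean per month x treatment. Two
balancing rules run in order: means from <= 2 replicates are dropped,
then means left unpaired across treatments within a month are dropped —
so every retained mean has a cross-treatment partner (which makes the
retained count necessarily even).

`fit_seasonal_model()` fits a maximum-likelihood linear mixed model via
`lme4::lmer` with one fixed-effect cell mean per photosynthetic type x
treatment x month and clade as a random effect dependent on month. The
default random structure is independent clade-intercepts per month
(`(1 | clade:month)`) — the minimal reading of "dependent on the month
of sampling"; a nested month-within-clade alternative is selectable.
All responses are log-transformed except instantaneous WUE ($A/E$),
which is modelled on the natural scale. Water potentials are negative:
they are negated before the log and re-negated after back-transformation
(sign handling is not standardised in the literature; this choice keeps
the log defined while preserving printed signs). Singular fits (clade
variance estimated at zero) are reported with a warning, never masked.

`bootstrap_cis()` draws parametric-bootstrap replicates: responses
simulated from the fitted model, refit with `lme4::refit`, cell
predictions back-transformed per draw, and percentile 2.5/97.5 limits
taken — for cell means and for the two contrast families (C4 − C3
within treatment x month; watered − rain-fed within type x month). A
contrast is "significant" when its interval excludes zero, the
operational meaning of confidence-interval significance marking at
P < 0.05. Refit failures above 10% abort with diagnostics. The
production default is 1000 simulations; the test suite and acceptance
script use 200, which widens Monte-Carlo error on the interval
endpoints by about a factor of two but leaves operating characteristics
measurable within the suite's runtime. Seeds and simulation counts are
recorded in the returned object and the pipeline manifest.

## The synthetic field

`generate_weather()` reproduces a November–April growing season by
monthly targets: mean of daily maxima 24/26/28/27/25/23 °C, mean of
daily minima RH 53/55/50/74/47/47%, rainfall totals
55/45/30/139/35/45 mm, for November through April respectively. The
January 28 °C, February 139 mm and 74%, November 53% and March–April
47% values anchor the generator to the season the analysis assumes; the
remaining months interpolate a warm-temperate summer-drought cycle.
Temperatures and humidities are recentred so monthly means hit targets
exactly; rainfall uses a first-order wet/dry chain with gamma amounts
rescaled to the monthly total exactly — stochastic daily structure,
exact printed totals. Midday conditions are daily maximum temperature
and minimum RH.

`generate_observations()` builds the 12-species x 4-clade x 2-treatment
x 8-block x 6-month design. Type-independent baselines (A = 9
umol m^-2^ s^-1^, gs = 0.105 mol m^-2^ s^-1^, predawn potential
−0.40 MPa, gradient −1.25 MPa) carry additive C4 − C3 offsets (+4,
+0.02, +0.08, +0.15 in the same units) and decline with the cumulative
water deficit of each treatment at type-specific rates — C3 faster for
conductance and assimilation, the structure under study, made explicit
so recovery is testable. With offsets zeroed and sensitivities
equalised (`effect_truth_null()`) the types are exchangeable. Lognormal
clade x month factors (SD 0.05) create the random-effect structure the
model assumes; record-level noise is mean-one lognormal (CV 0.30 for
fluxes, 0.12 for potentials), so arithmetic cell means stay on the
injected truth. Baselines, offsets and sensitivities were calibrated
once against the seasonal ranges the source experiment prints (C4
monthly mean A within 5.1–14.7 umol m^-2^ s^-1^; pooled gradients
within −0.73 to −1.59 MPa). Chamber bookkeeping fields are generated
with a few percent of records violating each QC rule; mortality follows
the per-species survivor table. One RNG stream per module, seeds
recorded in outputs.

What the generator does *not* emulate: the real station record and
within-day weather structure, spatial soil heterogeneity and soil
hydrology, instrument error structure of an open gas-exchange system,
predawn disequilibrium, or species-level drought idiosyncrasies beyond
a static multiplicative trait factor. Passing tests therefore establish
that the pipeline's arithmetic, bookkeeping and inference behave as
specified under the design's statistical structure — not that the
biological effect sizes would be recovered from any particular real
dataset.

## Verified operating characteristics

The test suite and `scripts/acceptance.R` recompute, from scratch, among
others: the 7 mm watering-depth worked example; energy-balance closure
below 0.1 W m^-2^ across 1000 random environments; the closed-stomata,
infinite-wind and linearized limits; ET0 against an independently coded
step-by-step oracle to 6 significant figures and monotonicity in demand
and radiation; Wilcoxon exactness against sign enumeration for n <= 12;
filter and balance counts on constructed fixtures; coverage of an
injected +4 umol m^-2^ s^-1^ January rain-fed contrast across 50 seeded
replicates with 200-draw bootstraps, and the false-positive rate of the
significance flag under the null truth; and machine-precision equality
of pipeline $K_\text{plant}$ with $E_\text{truth}/(-\Delta\Psi_\text{truth})$
in the noiseless limit.

## Known limitations

- The deficit index ignores soil hydrology by design; its absolute scale
  depends on the PPFD-to-shortwave conversion and the FAO-56 longwave
  defaults, which field metadata cannot pin down.
- The boundary-layer coefficient (0.135) and longwave geometry are
  defaults for a horizontal leaf over a lawn; other canopy geometries
  need different constants (both are arguments).
- Bootstrap percentile intervals condition on the estimated
  random-effect variance; with only four clades the variance is noisy
  and often estimated at zero (singular), which the package reports.
- `A/gs` unit relabelling conventions in the literature are not
  reproduced numerically.
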