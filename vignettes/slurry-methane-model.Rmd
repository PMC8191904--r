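---
title: "A multi-group mechanistic model of methane emission from stored slurry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-group mechanistic model of methane emission from stored slurry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slurrygas)
```

## Why this model

CH4 emission from stored slurry is controlled by three interacting clocks:
the supply of substrate (hydrolysis of particulate organic matter), the
growth and washout of the methanogenic community, and the management cycle
of the store (filling, threshold-triggered emptying, the residual left as
inoculum). A model with a single methanogen population cannot reproduce the
observed difference between short-term responses to temperature (the
current community, off its optimum) and long-term responses (community
turnover toward adapted groups). `slurrygas` therefore carries multiple
methanogen populations with individual temperature responses, plus an
optional sulfate reducer competing for the same substrate.

## State, processes and conservation

The reactor state is the slurry mass `M` (kg) and mass pools (g):
degradable particulate COD `Sp`, VFA (COD), sulfate-S, sulfide-S, total
ammoniacal N, and one biomass pool per group (COD basis), with cumulative
CH4, CO2 and H2S emission counters. Concentrations used by the kinetics
are pools divided by the *current* slurry mass — the consistent reading
when mass changes continuously during filling.

Eight processes form the Petersen matrix (signs per column, one rate per
row): hydrolysis `alpha(T) * Sp`; Monod VFA uptake per methanogen group;
double-Monod sulfate reduction; O2-transfer-limited surface respiration;
H2S volatilization proportional to surface area and unionized H2S;
first-order decay per group recycled into `Sp`; and inflow at `F_in` times
the influent composition. Because every flux is computed once and enters
each pool with its exact signed coefficient, linear invariants survive the
linear-multistep integrator to rounding: the COD residual audited by
`cod_balance()` is ~1e-15 on a year-long default run (the acceptance suite
requires < 1e-6). Methane closes the COD book at `P_CH4 = (1 - Y)/4` per
group; sulfide carries 2 g COD per g S, which is why the default sulfur
conversion factor of sulfate reduction is the yield-corrected electron
balance `(1 - Y_sr)/2` — with that choice sulfate-reducer scenarios
conserve COD exactly as well.

CO2 productivities default to acetate-like stoichiometry
(`(1 - Y) * 44/64` anaerobic, `(1 - Y_sr) * 88/64` for sulfate reduction)
and glucose-like combustion for the aerobic pathway (264/192). The
anaerobic coefficient lumps fermentation and methanogenesis, so it is
accurate at steady state or cumulatively, less so during VFA accumulation;
CO2 is pure bookkeeping and feeds back on nothing.

## Temperature, inhibition and speciation

`q_max` of every group and the hydrolysis constant follow CTM1: zero at
the cardinal limits, `rate_opt` exactly at `T_opt`, clamped to zero
outside `[T_min, T_max]` (the raw cubic changes sign there; no biology
beyond the cardinal limits). The half-saturation constant falls
exponentially with temperature, `K_S = KS_coef * k1 * exp(-k2 * T)`,
shared across groups up to the dimensionless `KS_coef`.

Inhibition is a product of four factors in [0, 1], all pluggable per
group. The pH factor is the ADM1-style normalized bell over a lower/upper
bound pair (defaults 6.0/8.5), equal to 1 at the midpoint; NH3, NH4+ and
H2S act noncompetitively, `1 / (1 + C / K_I)`, with defaults
`K_NH3 = 0.025` g N/kg (ADM1's free-ammonia constant), `K_NH4 = 10` g N/kg
(weak), `K_H2S = 0.15` g S/kg (0.55 for the sulfate reducer, which
tolerates its own product). Speciation is temperature-dependent: the NH4+
pKa uses an Emerson-type relation `0.09018 + 2729.92 / T_K`, the H2S pKa1
a van 't Hoff adjustment around 7.02 at 25 degC; both are config-exposed
constants.

## Management and enrichment

Filling at constant `F_in` makes the emptying time analytic:
`(M_max - M) / F_in`. The simulator therefore locates threshold events
exactly and applies the removal instantaneously rather than root-finding
across a solver discontinuity. Bulk pools scale by `f_resid`; each biomass
pool scales by `logistic(logit(f_resid) + a_enrich)`, so `a_enrich = 0`
treats organisms like solutes and `a_enrich = 5` at `f_resid = 0.5`
retains ~99.3% of a population — biofilm-mediated enrichment as a log-odds
increment. Observed slurry-mass series (the field-application pattern) are
handled by the forced-mass mode: interval increases become filling rates,
decreases become removal events with the implied residual fraction.

The default initial state is the post-removal residual (`f_resid * M_max`)
at influent composition, which makes the default scenario periodic from
the first cycle; it is overridable, and `run_to_periodic_steady_state()`
carries state across repeated forcing cycles (the shipped default is five
cycles, with early exit once per-cycle CH4 changes by < 0.1%).

## Default parameter set and provenance

Values fixed by the model description: yields 0.05 for all methanogens;
`alpha_opt = 0.02 1/d` at cardinal temperatures (0, 50, 60); the linear
`q_max,opt` rule (0 at 0 degC to 8 g/g/d at 40 degC, extrapolated);
influent biomass 0.01 g/kg for the mesophilic m3 (ten-fold the other
groups, reflecting gut-derived hydrogenotrophs in fresh excreta);
management 1000 kg/d into 33333 kg with `f_resid = 0.1` (a 30-d cadence);
20 degC and pH 7; VS-to-COD conversion 0.42 (degradable fraction) and
1.42 g COD/g VS.

Values this package had to choose (tagged `provenance: placeholder` in
`inst/extdata/paper-defaults.yaml`, all overridable): per-group cardinal
temperatures matched to the named species' growth ranges (m1 cold-adapted,
opt 18; m2 opt 28; m3 opt 37; m4 opt 43.5, midway between m3 and m5 by
construction; m5 opt 50; sr1 opt 38 with 1.2x the linear-rule rate and
yield 0.08); `k1 = 1.0` g/kg and `k2 = 0.05` /degC, which reproduce an
ADM1-like acetate `K_S` of ~0.16 g/kg at 37 degC; influent composition
47.7 g COD/kg particulate (80 g VS/kg through the VS conversion), 1 g/kg
VFA, 0.2 g S/kg sulfate, 2 g N/kg TAN; transfer coefficients sized so
surface respiration is a minor flux (~30 g COD/d on 33 m2) and H2S
exchange corresponds to a 1 cm surface film turned over daily.

## Numerical choices

Integration uses `deSolve::lsoda` (stiff-capable, automatic switching)
with `rtol = 1e-8`, `atol = 1e-6`, restarted at each removal event; the
output grid (daily by default) is decoupled from solver steps. Surface
respiration is gated by `Sp / (Sp + 0.01 g)` so a constant O2 flux cannot
drive the pool negative without introducing a hard switch; uptake rates
clamp negative pools to zero *consistently* (each flux computed once), so
overshoot protection never breaks conservation. Determinism is absolute:
no hidden randomness anywhere in the simulator; the only seeded component
is the noisy-seasonal forcing fixture.

The test suite cross-checks the adaptive path against a fixed-step
explicit Euler oracle (step 1e-4 d) across an emptying event, requiring
< 0.1% agreement per pool, and checks the assembled right-hand side
against an explicitly constructed Petersen matrix on random states.

## What the scenario generator does and does not emulate

The forcing fixtures (`make_forcings()`) produce constant, sinusoidal
(annual mean 12 degC, amplitude 10), step, composite and seeded-noise
temperature series at daily resolution — idealizations of seasonal
climate and of management interventions (cooling, barn-to-storage
transfer, acid dosing as a pH step with elevated influent sulfate during
treatment). They do not emulate: diurnal cycles, stratification or spatial
gradients in the store, rainfall dilution, crust formation, or correlated
measurement noise. Passing the qualitative suites therefore shows the
model mechanics produce the asserted directions under clean forcings, not
that field emissions are predicted quantitatively — the hydrolysis rate
constant alone spans more than an order of magnitude across reported
slurries.

Experiment problem sizes shipped with the package: 365-d scenarios for
sweeps and sensitivity, four warm-up cycles for seasonal runs, 500-d
acidification runs with the pH stepped down at day 60 and restored at day
180. These are the package's standard study conditions; all are arguments.

## Known limitations

* The default community at `f_resid = 0.1` and 20 degC sits close to the
  washout boundary: maximum net growth (`Y * q_max * I`, ~0.13/d) is not
  far above decay plus event washout (~0.097/d). Emission is then highly
  sensitive to anything scaling growth — halving `q_max,opt` or `Y`
  collapses the community, so those parameters can out-rank the hydrolysis
  constant in a +/-50% one-at-a-time tornado. Where the margin really sits
  depends on the placeholder constants above (inhibition constants,
  `k1`/`k2`, cardinal temperatures, influent TAN); users applying the
  model should calibrate them.
* Surface-crust processes, CH4 oxidation, N2O, and explicit lag-phase or
  acclimation mechanics are out of scope by design; hydrogen is merged
  into VFA consumption.
* TAN is transport-only (inflow, removal, speciation); no nitrification.
* The anaerobic CO2 coefficient is only exact cumulatively or at steady
  state (see above).
* Threshold mode requires constant `F_in`; time-varying production is
  supported through the forced-mass mode instead.
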