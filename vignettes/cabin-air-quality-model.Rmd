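---
title: "Modelling size-resolved particle and CO2 levels in vehicle cabins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling size-resolved particle and CO2 levels in vehicle cabins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabinaer)
```

## The model and its assumptions

`cabinaer` treats the cabin as a single well-mixed volume. For each of 25
particle size channels (midpoint diameters 10 nm to 2.53 µm) the cabin
concentration obeys a linear mass balance: filtered outside air — the
fan-driven supply `Qoa` plus the speed-induced passive ventilation `Qps` —
and crack-penetrating infiltration `Qinf·α` bring particles in; bulk
outflow, surface deposition (`Qdep = V·β`) and filtration of the
recirculated flow (`Qrec·η`) remove them. CO₂ follows the same structure
without filtration or deposition but with an occupant breath source
`N·Vbr·Cbr`. Everything is per channel; channels do not interact.

The assumptions this buys, and their price:

* **Well-mixed cabin.** Spatial gradients, seat-level differences and slow
  mixing after setting changes are not represented. Multi-point
  measurements in cabins support the assumption at steady state.
* **No aerosol dynamics.** Coagulation, condensation/evaporation and phase
  change are excluded; each channel keeps its particles. This is adequate
  for residence times of minutes but not for, say, dense smoke events.
* **No in-cabin particle sources.** Resuspension, smoking and occupant
  emission of particles are out of scope, so modelled cabin levels are
  bounded above by outdoor levels (the package asserts this invariant).
  Respiration losses of particles are likewise neglected — deposition
  losses are one to two orders of magnitude larger under driving
  conditions.
* **Channel-representative diameter.** Count↔mass conversion assumes all
  particles in a channel share the midpoint diameter and a common density
  (default 1000 kg/m³, configurable per scenario; effective densities of
  traffic aerosol are rarely known). No within-channel integration is
  performed — the filter table and balance operate on discrete channels.
* **CO₂ as a passive volume-mixing-ratio tracer.** The balance is linear in
  ppm with no temperature or pressure correction; recirculated CO₂ re-enters
  unchanged.

## Filter efficiency and the solution range

The packaged efficiency table (`load_filter_fixture()`) carries, per
channel, an upper and a lower limit spanning the range observed across
component tests of the same filter model, for four conditions: new or
500-h-aged, ionization on or off. Efficiencies drop markedly with ageing
and dip in the 100–350 nm region — the most penetrating particle size band
— and the table shows a sharp step between the 352 and 414 nm channels that
we transcribe as printed rather than smooth. One printed cell (new filter,
ionization off, 352 nm) has its lower limit 0.01 above its upper limit;
the table ships verbatim, and the `filter_spec()` constructor downgrades
the bound-ordering check to a warning for exactly this reason.

Because η is a range, the solution is a range. `eta_mode = "average"` (the
default) solves the balance once with each bound and averages the two
*solutions*. Averaging the solutions differs from solving with averaged
efficiencies because the steady state is nonlinear in η; the reported mean
cabin concentration is defined as the former.

The ultrafine aggregate counts channels with midpoint strictly below
100 nm (seven channels, 10–72 nm), matching the definition of UFP as
particles *smaller than* 100 nm; the cutoff is an argument of
`aggregate_distribution()` for users who prefer to include the 100 nm
channel.

## Airflow submodels and parameter defaults

**Passive ventilation.** Measured ram-pressure ventilation is linear in
speed with a published regression coefficient of 0.21. Taken literally as
0.21 m⁻¹ the expression is dimensionally inconsistent, so the package reads
it as an air-change rate per unit speed: ACH (h⁻¹) = 0.21 × speed (km/h),
i.e. `Qps[m³/h] = 0.21·vspeed·Vcabin`. At 100 km/h in a 4.1 m³ cabin this
gives ≈ 24 L/s, commensurate with the 23–86 L/s fan range — a strong
plausibility check. The coefficient is an argument of
`passive_ventilation()`.

**Envelope leakage.** Pressurization follows the inverse power law
`dPmech = ((Qoa+Qps)/kf)^(1/n)` and infiltration its forward form
`Qinf = Frev·kf·ΔPinf^n`, active only when the exterior aerodynamic
pressure `kp·a·e^(b·vspeed)` exceeds `dPmech`. The leakage coefficient
defaults to `kf = 18.78` m³/(h·Paⁿ), a pressurization-test value for
comparable modern vehicles (69.39, the maximum reported across vehicle
models, is retained for sensitivity work). The remaining envelope
parameters are not publicly available per vehicle, so the defaults —
`n = 0.66` (typical crack-flow exponent between laminar and orifice flow),
`Frev = 0.8`, `a = 1 Pa`, `b = 0.03` per km/h, `kp = 0.5` — are stand-ins
chosen once, inside literature-plausible ranges for sealed modern cabins,
and are labelled as such in `inst/extdata/vehicle_default.yaml`. They were
calibrated to reproduce the qualitative regime reported for such vehicles:
no infiltration while the fan supplies at least ~58 m³/h of outside air at
speeds up to ~103 km/h, with positive infiltration only under the
combination of weak pressurization (low fan, high recirculation) and high
speed. With these defaults that regime emerges from the pressure balance
itself and is locked in by property tests.

**Deposition.** Surface deposition rates in vehicles span roughly
0.5–12.6 h⁻¹ depending on size, airflow and interior. The default
per-channel profile is a parabola in log-diameter — high for the smallest
(diffusion-dominated) and largest (settling/impaction-dominated) channels,
minimum 0.9 h⁻¹ at 250 nm, maximum 11.9 h⁻¹ at 10 nm — a standard shape for
indoor deposition, kept inside the cited envelope. It is configuration
(`beta` in the vehicle file), not code.

**Zero-flow limit.** With fan off at standstill the leakage inverse is
undefined (log of zero); `mechanical_pressure()` returns the 0 Pa limit and
says so via a message.

## CO₂ parameters

The breath source uses `Vbr = 6.5` L/min — the midpoint of the 5–8 L/min
minute-ventilation range of seated adults at rest, appropriate for
passengers — and `Cbr = 40 000` ppm exhaled CO₂. The tunnel boundary
default of 716 ppm is the mean of two comparable published tunnel
measurements (710 and 722 ppm); open-road air defaults to 420 ppm. All are
plain arguments. At 100 % recirculation with occupants the steady state
does not exist (CO₂ grows without bound); `steady_state_co2()` raises an
error pointing to `transient_solve()`, which handles the accumulation case.

## Numerical choices

The balance system is linear with per-channel relaxation rates spanning
about two orders of magnitude (mild stiffness), so `transient_solve()` uses
deSolve's `lsoda` with `atol = 1e-9`, `rtol = 1e-8` — conservative for a
linear system, cheap at 26 states. Steady states are closed-form, never
iterated. A channel whose loss-plus-exchange denominator is zero has no
steady state; the error names the channel. `io_ratio()` refuses a zero
outdoor aggregate rather than returning infinity.

In the evaluation suite, FAC2 counts its endpoints as within a factor of
two (a prediction exactly half or exactly double the observation passes);
FB is signed so positive values mean underprediction, pinned by the
relation `P̄/Ō = (1 − 0.5 FB)/(1 + 0.5 FB)`; pairs with a zero value are
excluded from the logarithmic measures (MG, VG) with a message, and the
computation refuses to proceed if more than 10 % of pairs would be
dropped. Zero-variance series yield `r = NA` rather than an error, so the
remaining measures stay usable.

## The synthetic outdoor aerosol

No public dataset accompanies the model, so scenarios are built on a
generated boundary. `outdoor_aerosol_model()` describes traffic-influenced
outdoor air as a mixture of lognormal number modes discretized onto the
grid between geometric-mean channel edges, renormalized to conserve the
requested total count (truncation outside the grid span is reported). The
default — 55 % of counts in a 30 nm mode (GSD 1.8), 44 % at 90 nm
(GSD 2.0), 1 % at 500 nm (GSD 2.2), 30 000 N/cm³ total — mimics fresh
vehicular exhaust in a tunnel: most of the number concentration below
100 nm, most of the mass in the sparse accumulation/coarse tail. Generation
is deterministic; optional multiplicative channel noise is seeded.

What the generator does *not* emulate: correlated temporal variability,
meteorology-driven mode shifts, size-dependent composition and density, or
instrument artefacts. Tests passing on these boundaries therefore
demonstrate the correctness of the balance machinery and the qualitative
regimes — filter ageing raising cabin levels, the recirculation trade-off,
the pressurization envelope — not agreement with any specific road
campaign, which would require the campaign's own boundary measurements.

## Scales used in the packaged checks

The test suite solves randomized scenarios drawn over realistic driving
conditions (both cabin volumes, 0–120 km/h, 6–90 L/s outside air, all four
filter conditions, 0–3 occupants): 100 scenarios for transient/steady-state
cross-validation at 10⁻⁶ relative agreement, 80 draws of the
no-infiltration envelope, and 40 for the no-source concentration bound.
These sizes make the full suite run in seconds while leaving the property
space well covered.

## Known limitations

* Filter efficiency is independent of airflow rate in the model; component
  data behind the table were measured near 80 L/s, and real efficiencies
  fall at higher face velocities, so predictions at the High fan level
  inherit a bias the table cannot resolve.
* The aged-filter efficiencies, particularly with ionization, carry the
  largest component-test spread; the upper/lower solution range is the
  honest output there.
* Envelope parameters `a`, `b`, `kp`, `Frev`, `n` are stand-ins (above);
  absolute infiltration flows for a specific vehicle require its
  pressurization and coast-down data.
* Boundary conditions are constant per scenario; drive cycles must be
  composed by the user from piecewise runs.
* Particles outside 10 nm–2.5 µm and any coupling to the vehicle's climate
  energy system are out of scope.
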