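---
title: "Modelling ultrafine particles in a dispersing ship plume: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultrafine particles in a dispersing ship plume: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumeufp)
```

## The problem

Passenger ships maneuvering near harbors release exhaust that is extremely
rich in ultrafine particles (UFP, mobility diameter below 100 nm): a
primary nucleation mode (`Nuc_2`, peaking at 5–6 nm), an intermediate
soot-rich mode near 40 nm and an accumulation mode. As the plume dilutes,
sulfuric acid formed from co-emitted SO3 and from SO2 oxidation nucleates a
second, in-plume mode (`Nuc_1`, peaking near 1.5 nm) that grows by
condensation of H2SO4 and low-volatility organics while coagulation
scavenges it onto the larger exhaust modes. People living downwind are
exposed to these particles indoors after infiltration. `plumeufp`
implements this chain at desk scale: every input is generated
synthetically, and every process model is testable against closed-form
oracles.

## Two-stage dilution

**Stage 1 (jet expansion, 0–1 s).** The plume cross-section expands as
$S(t) = (\sqrt{S_0} + t\,\sigma_w)^2 - (t\,\alpha V_S)^2$ with the
entrainment velocity
$\sigma_w = \sqrt{(\alpha U)^2 + \sigma_{wt}^2 + (\alpha u_{jet})^2}$,
$\alpha = 0.1$, traffic turbulence $\sigma_{wt} = 0$ (irrelevant for ship
stacks) and $u_{jet} = V_S$ held constant over the one-second stage (no
decay law is available for the jet velocity; the stage is short enough
that the choice is second order). The dilution ratio is
$\mathrm{DR} = S(1\,\mathrm{s})/S_0$. With the ROPAX stack defaults
(funnel area $\pi/4$ m², exit velocity 30 m s⁻¹, exhaust temperature
580 K) the fourteen archived ship events give DR between 7.8 and 8.4 —
"approximately eight". The in-plume temperature after the stage is
$T_P = T_A + (T_E - T_A)/\mathrm{DR}$. If the printed cross-section
formula ever yields $S < S_0$ the result is floored at $S_0$ with a
warning: the expansion model does not describe that regime.

Coagulation competes with the expansion. The surviving number fraction
(dilution excluded) integrates monodisperse Smoluchowski loss inside the
analytically expanding cross-section,
$\dot n = -\tfrac12 K n^2 - (\dot S/S)\,n$, with a Fuchs kernel at the
exhaust count-median diameter (40 nm) multiplied by a polydisperse
enhancement factor `kernel_scale = 25`. The enhancement factor is the one
free parameter of this sub-model; it was fixed once so that typical events
retain 0.77–0.93 of their particles while the weak-wind event with the
highest exhaust concentration loses nearly half — the regime in which
coagulation stops being a minor correction.

**Stage 2 (power law).** Beyond 1 s, concentrations decay as
$y(x) = a\,x^{-b}$ with downwind distance $x$; $b$ is fitted from
receptor-like samples by least squares in log–log space (points at zero or
nonpositive concentration are dropped with a warning). Stability classes
map to $b$ = 1.40 (unstable), 1.26 (neutral) and 1.05 (stable) — values
chosen once inside the empirically reported range 0.99–1.47 whose average
is 1.26, higher in unstable and lower in very stable conditions. Every
plume quantity (gases, each particle section and component) relaxes toward
its background value as $\mathrm{d}C/\mathrm{d}t = -(b/t)(C - C_{bg})$,
integrated exactly over each step with the factor $((t+\Delta t)/t)^{-b}$,
which can never overshoot the background. The plume height grows as
$H_P(t) = \sqrt{H_{P,0}^2 + (a'(10^{-3} U t)^b)^2}$ with $H_{P,0} = 5.5$ m
and $a' \in \{110.62, 86.49, 61.14\}$ by stability class.

## Sectional aerosol dynamics

The particle population lives on 120 fixed log-spaced sections between
1 nm and 10 µm (the lower bound must contain the 1.5-nm `Nuc_1` peak).
Each section carries a number concentration and per-component masses
(soot, NV-POM, SV-OM, ELV-OM, sulfate, water). The operator sequence per
0.1-s step is fixed: chemistry → nucleation → condensation → coagulation →
dry deposition → dilution. Halving the step changes 900-s diagnostics by
far less than the tolerances used in the tests, so the splitting error is
acceptable at this step.

**Nucleation.** Binary homogeneous H2SO4–H2O nucleation via the published
polynomial parameterization of classical theory (critical-cluster mole
fraction, rate, cluster content, cluster radius), applied up to 400 K as
appropriate for exhaust. The rate is capped at the fit's validity ceiling
(10¹⁰ cm⁻³ s⁻¹) and limited by the available sulfuric acid each step —
this limiter, not the cap, usually ends the initial burst. New particles
are inserted at the critical-cluster diameter with H2SO4 composition; the
organic-involving variant (`NUHET`) scales the rate by an
organic-availability factor $1 + k_{org} C_{org}$ ($k_{org} = 2\times
10^{-13}$ cm³, a placeholder magnitude giving a few-percent enhancement)
and adds one organic molecule per cluster.

**Condensation.** Mass transfer uses the analytical-predictor scheme: the
vapor is updated implicitly, $C' = (C + \Delta t \sum_i L_i
C_{eq,i})/(1 + \Delta t \sum_i L_i)$, then per-section fluxes
$\Delta t\,L_i (C' - C_{eq,i})$ move mass, with evaporation limited to the
mass present. Gas + particle mass of each species is conserved by
construction. Equilibrium concentrations combine a Clausius–Clapeyron
saturation pressure, a Raoult mole-fraction term over the absorbing phase
(everything but soot) and a Kelvin term. The three organic vapors are the
n-alkane proxies C22H46, C28H58 (feeding SV-OM) and C34H70 (a lubricant
constituent feeding ELV-OM), with saturation pressures of about 1e-4,
1e-7 and 1e-11 Pa at 298 K and vaporization slopes of 14000, 17000 and
20000 K. Sulfuric acid is involatile. After condensation or nucleation the
state is projected back onto the fixed section centers: each section's
content is split between the two sections whose center volumes bracket its
mean particle volume, conserving number and every component mass exactly;
a consistency check flags mean-volume drift beyond a factor of two.

**Coagulation.** Fuchs transition-regime Brownian kernel over all section
pairs. Each colliding pair produces one particle of combined center
volume, volume-split between the bracketing sections; the parents'
component masses travel with it, so component mass is conserved to
machine precision and number strictly decreases. Losses are damped with
the exponential-integrator factor $(1 - e^{-\Delta t\lambda})/\Delta
t\lambda$ per section (production explicit, loss implicit), keeping the
state positive for any step size. With a constant kernel and a
monodisperse start the scheme tracks the Smoluchowski closed form
$N(t) = N_0/(1 + \tfrac12 K N_0 t)$ within 2% over 100 steps.

**Deposition and water.** Dry deposition is a first-order loss
$v_d(D_p)/H_P(t)$ with a smooth-surface resistance parameterization
(friction velocity 0.3 m s⁻¹); the process is named but unspecified in the
source material, so the scheme is a standard, configurable choice. Water
is diagnosed, not transported: a single-parameter hygroscopic-growth
closure on the sulfate volume ($\kappa = 0.9$), evaluated at snapshot
times with water activity clamped at 0.95.

**Chemistry.** Only the pathways that matter to the condensable-vapor
supply are kept: SO3 hydration to H2SO4 (pseudo-first-order, 10 s⁻¹ — fast
against dilution while numerically benign at the 0.1-s step, so >99% of
SO3 converts within the first second), SO2 + OH with the standard
termolecular rate, and the NO–NO2–O3 photostationary state solved as a
quadratic conserving NOx and total oxidant (at zero photolysis it reduces
to titration). OH and the NO2 photolysis frequency are prescribed per
event from month and hour (daylight 3×10⁶ cm⁻³ OH, dark 10⁴ cm⁻³); a full
kinetic mechanism is deliberately out of scope. The background gas state
is repartitioned to the photostationary state so that it is an exact fixed
point of the in-plume chemistry.

## What the generators emulate

The fixtures module generates every input. The exhaust preset solves the
`Nuc_2` weight so that exactly 29% of the continuous number distribution
lies below 25 nm, with mode medians 5.5/40/100 nm and widths 1.35/1.35/1.55
(only the peaks are constrained by observation; the widths and the
40-nm-mode composition — soot plus nonvolatile POM, consistent with about
two thirds of fresh exhaust particles being nonvolatile — are package
choices). `Nuc_2` is 20% liquid H2SO4 and 80% primary organics by mass
(100% H2SO4 under `HSULF`). The Helsinki background preset totals
5400 cm⁻³ with an aged-urban composition; it is a synthetic stand-in, not
a measurement table. Per-event initial concentrations (diluted exhaust PN
of 1–10 ×10⁶ cm⁻³, SO3-derived H2SO4 of 1–5 ×10¹⁰ cm⁻³, organic vapors at
7/7/11 times the H2SO4 potential) are synthetic emission-data stand-ins
chosen once to reproduce the stated ranges. None of this reproduces the
turbulent heterogeneity of a real plume: concentrations are uniform across
the modeled cross-section, so nonlinear rates (coagulation in particular)
are evaluated at the mean. Passing tests therefore demonstrate internal
consistency with the stated model, not fidelity to any particular measured
event.

## Exposure stage

Simulated UFP concentrations along the centerline are averaged into 40-m
rings and inserted uniformly into a ±15° sector out to 3600 m — the
centerline insertion deliberately overestimates the outer plume, as the
source methodology does. Daily means assume five plume-minutes per
scheduled ship passage and background otherwise. Residential exposure is
$E_i = F_{inf} \cdot C_i \cdot P_i \cdot f_{home}$ with infiltration
factor 0.56 and a flat at-home fraction of 0.6 (hour-resolved activity
tables are not reproduced; the fraction is configurable). Excess mortality
risk is linear: 4% per 6250 cm⁻³ of daily mean UFP increment. Ring–sector
values are resampled to the 100-m population raster by 5×5 sub-cell point
sampling; the rotation-invariance property is exact for quarter-turn
rotations, which is what the tests exercise.

## Numerical choices and problem sizes

Simulations use the 0.1-s step for 900 s of plume travel starting at
t0 = 1 s, with snapshots every second. The test-suite runs use shorter
horizons where the property under test allows it: scenario contrasts are
evaluated at 30 s of travel, seasonal growth-rate ordering over 300 s, and
the closed-form dilution oracle over the full 900 s. The tracked `Nuc_1`
growth rates are reported in nm h⁻¹ from a linear fit to the mode-peak
diameter; on the synthetic presets the winter event grows faster than the
summer event, as expected from slower dilution and colder condensation,
but the absolute rates exceed the field-derived values — the generator's
vapor loadings, not the growth mechanics, set that scale.

## Known limitations

* The organic-involving nucleation variant is a scaling placeholder, not a
  mechanistic cluster model.
* SV-OM is carried as one component fed by two vapors sharing it equally;
  species-resolved particle composition is not tracked.
* Exhaust emission data are synthetic stand-ins; absolute masses and
  growth rates inherit their uncertainty.
* The exposure stage models a single microenvironment (home); others are
  configurable stubs only.

## Worked example

```{r example, eval = FALSE}
ev <- make_event("J_20100811")
stack <- stack_spec()
first_stage_dilution_ratio(stack, ev)        # ~8.1
initial_plume_temperature(280, 580, 8)       # 317.5 K
traj <- simulate_plume(ev, duration_s = 120)
summarize_plume(traj, 30)$np_number_cm3
```
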