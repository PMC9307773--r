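---
title: "A dynamic biofilter model with Haldane kinetics and steady-state multiplicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic biofilter model with Haldane kinetics and steady-state multiplicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the model

A biofilter passes contaminated air upward through a moist packed bed
(compost and wood chips here) colonized by pollutant-degrading microbes.
The pollutant — toluene in the configurations this package ships — dissolves
into thin biofilms on the packing, diffuses inward, and is consumed. The
model couples four balances:

**Gas phase (plug flow).** With superficial velocity $v$ (m/h), bed height
$Z$, porosity $\varepsilon$, packing bulk density $\rho_{bulk}$
(kg/m$^3$) and specific biofilm area $A$ (m$^2$/kg),

$$\frac{\partial C_g}{\partial t}
  = \frac{-v\, \partial C_g/\partial z \;-\; \rho_{bulk} A L \bar r}{\varepsilon}.$$

Axial dispersion is neglected; the inlet value is pinned to the scheduled
concentration.

**Biofilm (planar reaction–diffusion).** On the scaled depth coordinate
$x' = x/L \in [0,1]$ (0 = substratum, 1 = gas interface),

$$\frac{\partial C}{\partial t}
  = \frac{D}{L^2}\frac{\partial^2 C}{\partial x'^2} - r(C), \qquad
  r(C) = \frac{V_{max}\, C\, \rho_{bio}}{K_s + C + C^2/K_I},$$

with Henry's-law coupling $C(1) = C_g/H$ and zero flux at the substratum,
$\partial C/\partial x'|_{x'=0} = 0$. The Haldane (substrate-inhibited) rate
peaks at $C^\* = \sqrt{K_s K_I}$ and declines beyond it; this is the
mechanism that lets a sufficiently thick film hold two stable states at one
gas concentration: a *high-activity* state (steep internal gradient, most of
the film near the rate optimum) and a *low-activity* state (film saturated
at a high, strongly inhibited concentration). $\bar r$ is the depth average
$\int_0^1 r(C)\,dx'$ evaluated by the grid's quadrature.

**Biomass.** Per axial node, $dX/dt = (\mu - a)X$ with
$\mu = \mu_{max}\, f_H(C)\, N/(K_N + N)$, where $f_H$ is the Haldane factor
and $N$ the inorganic nitrogen of the packing. Film thickness follows the
biomass, $L = X/(A\rho_{bio})$, so films grow and shrink with the local
balance of growth and decay.

**Nitrogen.** $dN/dt = k_{min} N_{org} - k_{upt} N - \mu f_N \rho_{bio} A L$:
mineralization of the packing's organic nitrogen feeds a pool that
background uptake and biomass growth drain. Because
$\mu f_N \rho_{bio} A L = \mu f_N X$, sustained growth is capped by the
mineralization supply; with the bundled constants the biomass carrying
capacity is $k_{min}N_{org}/(f_N a) \approx 5.9$ g/kg, i.e. films plateau
near $L \approx 5\times10^{-5}$ m.

## Which concentration drives growth

The growth expression is the one genuinely open modelling choice: the
Haldane factor in $\mu$ can be evaluated at the local gas-phase
concentration (`gas_literal`), at the biofilm surface concentration
$C_g/H$ (`interface`), or as the depth average of the factor over the film
profile (`biofilm_average`). All three are implemented;
`growth_concentration_mode` selects one. The default is `gas_literal`
because it is the literal form of the growth equation and because it is the
only variant that reproduces the defining qualitative feature of the ramp
scenario: a *discontinuous, single-day* collapse of removal efficiency. The
depth-averaged and interface variants both produce a gradual multi-day
breakthrough instead — the averaged Haldane factor collapses once a film
becomes diffusion-limited, which redistributes growth and smears the
transition.

## Discretization and numerics

* **Orthogonal collocation** in both coordinates: interior nodes at the
  roots of the shifted Legendre polynomial, both endpoints appended;
  differentiation matrices by barycentric Lagrange differentiation;
  quadrature weights by exact integration of the Lagrange basis. The node
  counts (`n_biofilm = 10`, `n_axial = 25`, totals including boundary
  nodes) match the configuration the presets were fitted with and are
  configurable.
* **Boundary conditions by substitution.** The film surface value is not a
  state: it is set to $C_g/H$ at every evaluation. The substratum value is
  eliminated through the zero-flux row of the first-derivative matrix, so
  each film contributes `n_biofilm - 2` differential states and the whole
  column is one stiff ODE system (no DAE machinery), integrated with a
  sparse-Jacobian BDF method (`deSolve::lsodes`) and restarted at each
  schedule breakpoint so the piecewise-constant inlet enters exactly.
* **Regularized rate evaluation.** The spectral representation of a
  boundary-layer profile on 10 nodes oscillates slightly below zero on its
  inner tail. The rate factor is therefore evaluated with a signed numerator
  and a smoothed denominator,
  $C/(K_s + \sqrt{C^2+\epsilon^2} + C^2/K_I)$ with $\epsilon = 10^{-4}$
  g/m$^3$: a small negative excursion yields a small restoring rate, the
  scheme stays discretely conservative, and the function is smooth through
  zero (a hard clamp makes the BDF integrator thrash on Jacobian kinks; in
  our profiling a clamped rate cost two orders of magnitude more CPU).
  At physical concentrations the regularization error is below $10^{-6}$
  relative.
* **Degenerate films.** The depth equation divides by $L^2$; films below
  $10^{-12}$ m are bypassed (no removal, growth driven by the interface
  concentration). The clean-bed initial film ($\approx 3\times10^{-8}$ m) is
  far above the cutoff.
* **Steady films and continuation.** The steady boundary-value problem is
  solved by damped Newton iteration from two cold seeds — a *depleted*
  first-order (cosh) shape and a *saturated* uniform profile — with
  pseudo-transient relaxation as a fallback when a seed lies outside every
  Newton basin. The multiplicity scan sweeps the gas concentration upward
  continuing the high-activity branch and downward continuing the
  low-activity branch, reports every distinct converged state, and brackets
  the fold concentrations by bisection. Branch stability can be verified by
  short time integration from a perturbed profile (`label_stability`).
* **Advection scheme.** Spectral differentiation of the axial profile is the
  default (matching the collocation formulation throughout); a first-order
  upwind finite-volume alternative (`advection_scheme = "upwind"`) is
  provided because spectral advection of near-discontinuous profiles
  oscillates — at >99.9% removal the outlet value rides on such
  oscillations. The upwind scheme is monotone but numerically diffusive; it
  is the robustness escape hatch and a cross-check, not the default.

## Parameters

All rates are per hour; concentrations g/m$^3$ (gas, film) or g/kg compost
(biomass, nitrogen). The three presets (`bf_preset()`) share every kinetic
and nitrogen constant ($V_{max}=0.3$, $K_s=0.05$, $K_I=2.7$,
$\mu_{max}=0.1$, $a=0.0014$, $H=0.25$, $v=3.63$ m/h, $\varepsilon=0.55$,
$\rho_{bio}=10^5$ g/m$^3$, $N_{org}=14.98$, $k_{min}=7\times10^{-5}$,
$k_{upt}=2.2\times10^{-3}$, $K_N=0.5$, $f_N=0.126$, $X_0=0.003$ g/kg) and
differ in the biofilm area $A$ (0.95 / 1.1 / 0.2375 m$^2$/kg), biofilm
diffusivity $D$ ($1.5\times10^{-10}$ / $10^{-11}$ / $10^{-12}$ m$^2$/s) and
bulk density (555 / 555 / 306 kg/m$^3$). Configs accept $D$ in m$^2$/s and
convert to the internal m$^2$/h at load time. Two values are package
decisions where the sources were silent or inconsistent:

* `n_inorg_0 = 0.916` g N/kg — the packing's measured nitrate+nitrite
  content — is the default initial inorganic nitrogen (overridable).
* The organic nitrogen content is interpreted as g N per **kg** compost,
  consistent with the packing's total-nitrogen analysis and with $K_N$'s
  units.
* Bed height 0.25 m and diameter 0.10 m; residence time is computed from
  geometry and velocity ($Z/v \approx 4.1$ min), not taken as an input.

### The ramp scenario's diffusivity

`ramp_scenario_params()` is the steady-increase preset with
$D = 1.5\times10^{-10}$ m$^2$/s instead of the tabulated
$1.5\times10^{-11}$. The reason is a capacity bound, not a fit: the largest
flux a semi-infinite film can draw is
$J_{max} = \sqrt{2D\int_0^{C_s} r(c)\,dc}$, giving a column removal ceiling
of $\rho_{bulk} A J_{max} \approx 93$ g/m$^3$/h at
$D = 1.5\times10^{-11}$ — below the $\approx 115$ g/m$^3$/h load the column
carries at >99.9% removal just before the reported jump, so that
configuration cannot produce the ramp behaviour at all (simulated: removal
erodes from day 13 and never jumps). The accompanying description of the
ramp run states that only $A$ was changed (0.95 → 1.1) from the
bistable-column configuration, whose diffusivity is $1.5\times10^{-10}$;
the presets themselves stay verbatim.

## What the ramp run shows — and its known limitation

Under daily inlet increments of 0.272 g/m$^3$, the simulated column holds
removal efficiency above 99.9% for five weeks while biofilms grow toward the
nitrogen-limited carrying capacity, then collapses by >60 percentage points
within a single day, and does not recover when the inlet is stepped back
down (hysteresis — the signature of a steady-state transition rather than a
biofilm collapse). Hourly snapshots show the mechanism: at the crash hour,
films that carried a steep internal gradient (interface/substratum
concentration ratio above 5) saturate to a near-flat profile (ratio below
1.2) within two hours.

The *location* of the jump is the model's known limitation. The simulated
crash arrives on day 36 at an inlet of 9.5–9.8 g/m$^3$, several days and
about 1.6 g/m$^3$ above the transition the configuration was fitted to
(observed in the 7.7–8.5 g/m$^3$ range). Per-node diagnostics show why: the
nodes behind the inlet region also grow films near carrying capacity, and
this mid-column reserve keeps absorbing the load for several days after the
inlet-end films have already saturated; the crash occurs only when the
saturation front exhausts the reserve. Every documented ambiguity was
explored — the three growth modes, total-vs-interior node-count
conventions, spectral vs upwind advection, and both diffusivity readings —
and none moves the crash earlier than day 36 without destroying the >99.9%
plateau. The discrepancy is reported as-is; the pre- and post-jump removal
efficiencies themselves reproduce within a few percentage points.

## The synthetic-observation generator

`synthesize_observations()` emulates daily gas-chromatograph sampling of
the outlet: at each end-of-day sample it draws `n_replicates` (default 3)
independent Gaussian replicates with sd `noise_sd` (default 0.10 g/m$^3$,
the measurement repeatability of the fitted configurations) and reports
replicate means with their standard errors (expected
$0.10/\sqrt{3} \approx 0.058$ g/m$^3$). It emulates *measurement*
repeatability only: no drift, no inlet fluctuation, no within-bed
heterogeneity, no autocorrelation. Tests built on it therefore validate the
statistics pipeline (RMSE, $r^2$, interpolation to observation times), not
the model's fidelity to any real column.

## Problem sizes used by the test suite

The suite runs the full 40-day ramp once (25 axial × 10 film nodes, ~270
stiff states, about a minute) and shares it across the jump, hysteresis,
saturation and mass-balance checks. Steady-film oracle comparisons use 30
collocation nodes against a 500-point finite-difference multi-start solver
over gas concentrations 0.01–20 g/m$^3$ for all three presets. Analytic
limits (no-reaction pass-through, first-order plug-flow/cosh closed forms,
abiotic nitrogen equilibrium, Haldane optimum location) run in seconds.

## Limitations

Oxygen is assumed non-limiting; single degrader species; no detachment,
shear, moisture or temperature dynamics; no axial dispersion or pressure
drop; no adsorption to the packing. The biomass yield constant is carried
in the parameter set for completeness but does not enter the growth
equations, which use $\mu_{max}$ directly. Fold-point locations of the
coarse 10-node film differ from the fully resolved film's (the resolved
high-activity branch extends to higher concentrations); node counts are
part of the model configuration, matching standard practice for this model
family.
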