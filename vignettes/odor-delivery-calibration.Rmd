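---
title: "Calibrating odor delivery: the mass-transfer model behind odorcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating odor delivery: the mass-transfer model behind odorcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorcal)
```

## The problem

Insect olfactory experiments routinely report stimulus "intensity" as the
amount of odorant loaded into the source. Because evaporation rates vary
by orders of magnitude across compounds and devices, that number says
little about the gas-phase concentration reaching the antenna, which
frustrates cross-study comparison, threshold estimation, and the
reproduction of ecologically realistic stimuli. `odorcal` models the
delivery chain of a common device class — a vial of odorant solution in
mineral oil, flushed by a valve-gated airflow into a carrier stream — so
that delivered concentrations can be predicted, and the device calibrated,
from a small number of physical parameters.

## Model and assumptions

The device is a chain of well-mixed compartments: source liquid (volume
$V_l$), source headspace ($V_h$), and a transport tube ($V_c$), with the
liquid surface (area $A$) as the single mass-exchanging interface.

**Henry equilibrium.** Solutions are assumed at infinite dilution, so the
closed, equilibrated source obeys $C_{h0} = K_{hl}\,C_{l0}$ with a
dimensionless, compound-specific air–solvent partition coefficient
$K_{hl}$. Activity-coefficient corrections for concentrated solutions are
out of scope.

**Two-film interfacial flux.** The net flux towards the headspace is
$J = (K_{hl} C_l - C_h)\,k_{glob}$ with the two film resistances in
series, $1/k_{glob} = 1/k_h + K_{hl}/k_l$. Transfer through the interface
itself is instantaneous, and bulk phases are uniform. $k_h$ and $k_l$ are
treated as properties of the device (independent of compound identity) —
the assumption that makes one calibration transferable to any compound of
known $K_{hl}$.

**Dynamics.** In dimensionless variables ($Y_l = C_l/C_{l0}$,
$Y_h = C_h/C_{h0}$, and $Y_c$ = tube concentration also normalised by
$C_{h0}$):

$$\frac{dY_l}{dt} = -\frac{A k_{glob} K_{hl}}{V_l}(Y_l - Y_h), \qquad
\frac{dY_h}{dt} = \frac{A k_{glob}}{V_h}(Y_l - Y_h) - \frac{Q_s}{V_h} Y_h,$$
$$\frac{dY_c}{dt} = \frac{Q_s}{V_c} Y_h - \frac{Q_c}{V_c} Y_c,$$

with $Q_s = 0$ while the valve is closed and initial state
$Y_l = Y_h = 1$, $Y_c = 0$. Because $C_{l0}$ and $C_{h0}$ cancel, stimulus
*shape* is independent of the loading; only its scale changes. Setting
$dY_h/dt = 0$ with $Y_l = 1$ gives the pseudo-stationary plateau
$Y_{h,psr} = A/(A + Q_s/k_{glob})$, which the simulator reproduces as its
stationary limit by construction. Normalising $Y_c$ by $C_{h0}$ makes its
open-valve plateau $Y_{h,psr} \cdot Q_s/Q_c$ — the carrier dilution appears
as a factor rather than a rescaling, which keeps the three trajectories
directly comparable on one axis.

The transport compartment is a single well-mixed cell by default
(justified by the turbulent merging of 8 air streams at its entry);
`simulate_device(n_cells = )` chains several cells for studies of reduced
axial mixing. The plateau is unaffected; only the front sharpens.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| $K_{hl}$ | — | per compound | Henry volatility; panel spans $1.9\times10^{-7}$–$1.1\times10^{-2}$ |
| $k_h$ | m/s | $1.15\times10^{-2}$ | calibrated headspace-side coefficient of the reference device |
| $k_l$ | m/s | $1.24\times10^{-5}$ | calibrated liquid-side coefficient |
| $A$ | m² | $1.38\times10^{-4}$ | measured interface area; the disc of $d = 13.2$ mm gives $1.368\times10^{-4}$, so an explicit `area` field overrides the disc default |
| $Q_s$, $Q_c$ | m³/s | 200, 1600 mL/min | source and total carrier airflow (8 lines) |
| $V_l$, $V_h$, $V_c$ | m³ | 1, 3, 12.7 mL | compartment volumes |
| $D$ | m²/s | $8.54\times10^{-6}$ | panel-average gas diffusivity; per-compound values override |
| Sc | — | 1.9 | panel-average Schmidt number used when $D$ is not given |
| $T$, $P$ | K, Pa | 295.15, 101325 | operating temperature (22 °C) and pressure for ideal-gas conversions |

All computation is SI internally; `ml_to_m3()`, `ml_min_to_m3_s()`,
`mm_to_m()`, `cm2_to_m2()` convert the bench units accepted in YAML device
configs.

## Numerical choices

- **Integration.** Rate constants span 6+ orders of magnitude across the
  compound panel, so the simulator uses a stiff BDF integrator
  (`deSolve::ode(method = "bdf")`) at `rtol = 1e-8`, `atol = 1e-12`. The
  adaptive Adams/BDF switcher (`lsoda`) fails its own dense-output check
  on long closed-valve segments of this system, so the plain BDF method is
  used throughout. Valve transitions are instantaneous $Q_s$ steps and the
  integration restarts at each segment boundary, so discontinuities are
  never smeared across a step.
- **Lifetime detection.** The source lifetime is the first time $Y_h$
  drops below $0.95\,Y_{h,psr}$. The trajectory starts at $Y_h = 1$ above
  the threshold and approaches the plateau from above, so a naive root
  search cannot false-trigger; nevertheless the detector runs in two
  phases (first locate the approach within 1% of the plateau, then the
  downward crossing, both by `lsodar` event detection) to stay robust on
  pathological parameter sets where depletion outruns equilibration.
  Horizons default to 30 days; a non-crossing run returns a censored
  result rather than a number.
- **Calibration fit.** $Y \sim A/(A + e^B + e^C K_{hl})$ is fitted by
  Levenberg–Marquardt with a heuristic start ($B$ from the low-$K_{hl}$
  plateau level, $C$ from the highest-$K_{hl}$ point) plus a 5×5 log-grid
  multi-start; the best residual sum of squares wins. Back-transformed
  estimates $k_h = Q_s/e^B$, $k_l = Q_s/e^C$ carry Wald intervals that are
  symmetric on the log scale. Degenerate designs (fewer than 3 points, or
  no points on the declining branch) raise an error or an
  identifiability warning rather than returning silently absurd $k_l$.
- **Error-variance model.** The default fit is ordinary (unweighted) least
  squares on untransformed $Y$. Detector noise on signals spanning decades
  is, however, typically multiplicative; for such data
  `fit_transfer_coefficients(variance = "relative")` refits with
  $1/\hat{y}^2$ weights (constant relative error) so that the reported
  intervals are calibrated against that noise structure. Under the
  package's own multiplicative-lognormal generator the relative-variance
  intervals attain near-nominal coverage, while constant-variance
  intervals undercover because the pooled residual variance is dominated
  by the precise high-$K_{hl}$ points. The test suite quantifies this.
- **PRV estimator.** The phase ratio is defined as headspace over liquid
  volume, $\beta = (V_{vial} - V_{liq})/V_{liq}$ — the convention under
  which $1/\text{area}$ is linear in $\beta$ and $K_{hl}$ equals the
  regression slope divided by its intercept. The nonlinear form
  $\text{area} = p_1/(\beta + 1/K_{hl})$ is fitted with log-parametrised
  $(p_1, K_{hl})$; since $p_1$ enters linearly it is profiled out to give
  consistent starts, and near-flat series (the $K_{hl} < 10^{-4}$ regime
  where PRV is known to fail) fall back to a 1-D profile optimisation
  with a curvature-based standard error and a "poorly identified"
  warning.
- **LC estimator.** The FID calibration is a log–log linear regression;
  the partition coefficient is the zero-intercept slope of headspace on
  liquid concentration. Multi-series data are pooled with cluster-robust
  (CR1) standard errors, series as clusters — a simpler, dependency-light
  stand-in for a generalized-estimating-equations fit that leaves the
  point estimate within the span of the per-series slopes.
- **Flow regimes.** The Sherwood correlation
  $k_h = D\,a\,\mathrm{Re}^b\,\mathrm{Sc}^{0.33}/d$ uses the classical
  coefficient pairs (laminar 1.86/0.33, intermediate 0.664/0.5, turbulent
  0.04/0.75). Automatic regime selection uses the standard pipe-flow
  bounds Re < 2100 / 2100–10000 / > 10000, resolving an exact threshold to
  the lower regime; an explicit `flow_regime()` always overrides. The
  correlation is a trends-only tool: narrow vial inlets generate more
  turbulence than the straight-pipe Reynolds number suggests, so
  correlation-predicted $k_h$ can sit an order of magnitude below a
  calibrated value and direct calibration is required for quantitative
  work.
- **Design sweeps.** Sweeps over diameter and airflow need a volume
  policy; the default keeps geometric similarity, $V_h = 0.8\,d^3$ (0.8 mL
  at $d = 10$ mm through ~22 L at 300 mm) with $V_l = V_h/3$, both
  configurable. Lifetimes in sweeps use the quasi-steady closed form
  $\ln(1/0.95)/\lambda$ with
  $\lambda = (A k_{glob} K_{hl}/V_l)(1 - Y_{h,psr})$, falling back to the
  full ODE when the required 100× timescale separation fails.

## What the synthetic generators emulate — and what they do not

Every estimator in the package has a seeded generator that is its exact
forward model: `gen_plateau_observations()` (plateau fractions from
`psr()` under multiplicative lognormal noise), `gen_pid_trace()`
(simulated outlet concentration × detector gain, with an optional
first-order low-pass emulating the PID's slow response to low-volatility
compounds, gated by the valve state since no air leaves a closed source),
`gen_prv_series()` and `gen_lc_series()` (vial and detector forward
models, 15 vials of 30 µL–1 mL aliquots in 20-mL vials, 3–4 concentration
levels × 3 replicates). Multiplicative lognormal is the default noise
because the emulated signals are positive and span decades; seeds are
mandatory arguments and generators restore the session RNG state.

Passing round-trip tests against these generators demonstrates that the
estimators invert their own forward models — a necessary condition, not a
field validation. Real data add effects deliberately left out:
adsorption/desorption on tubing and detector surfaces (the dominant cause
of slow signal tails for heavy compounds), chromatographic drift and
co-elution, temperature fluctuations, and detector nonlinearity beyond a
power law. Calibration against real measurements remains indispensable;
the generators exist so that every code path is exercised and every
estimator's statistical behaviour (bias, interval coverage) is measurable
without instruments.

## Problem sizes used by the test suite

The suite simulates at the reference-device scale throughout: 9-compound
calibration designs (the panel members with an observable plateau), 200
replicates for interval-coverage measurement, 200 replicates per
$K_{hl}$ decade for PRV bias, minute-scale stimulation protocols at 20–50
samples/s, and lifetime integrations up to 30 simulated days. These sizes
keep the full suite in the tens of seconds on one CPU while leaving the
statistical checks enough power to be meaningful.

## Known limitations

- No wall-binding model: predicted stimulus shapes for the least volatile
  compounds are sharper than PID recordings, which convolve the true
  dynamics with detector adsorption. `gen_pid_trace(tau_pid = )` emulates
  the filtering but nothing in the package infers it.
- $k_l$ is assumed independent of geometry and airflow in sweeps; fast
  inlet jets can stir the liquid and raise $k_l$ on small sources.
- The Sherwood correlation is for straight-pipe flow and underestimates
  turbulence in vials fed through needles; treat correlation-based
  $k_h$ as order-of-magnitude.
- Infinite-dilution thermodynamics only; concentrated or self-associating
  solutions violate the Henry assumption.
- The PRV estimator is uninformative below $K_{hl} \approx 10^{-4}$ (flat
  response in $\beta$); the package warns and the liquid-calibration
  route should be used instead.
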