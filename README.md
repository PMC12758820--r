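# odorcal

Predict and calibrate the **absolute odorant concentration** delivered by
simple vial-based odor delivery devices of the kind used in insect
electrophysiology and chemical ecology.

Olfactory stimuli are usually reported as the amount of odorant loaded
into the source, but the concentration actually reaching the preparation
depends on the compound's volatility and on the device: the airflow
dilutes the source headspace while interfacial mass transfer refills it
from the liquid. `odorcal` implements a two-film mass-transfer model of
this process, so that a source of known composition can be translated
into a delivered gas-phase concentration (mol/m³ or ppbv), and a device
can be designed or calibrated for a target stimulus.

## The model

An odor source is a vial holding a volume *V<sub>l</sub>* of odorant
solution (concentration *C<sub>l</sub>*) under a headspace *V<sub>h</sub>*,
separated by the liquid surface of area *A*. At rest, Henry's law sets the
headspace concentration *C<sub>h0</sub> = K<sub>hl</sub> C<sub>l0</sub>*,
where *K<sub>hl</sub>* is the dimensionless air–solvent partition
coefficient. During stimulation an airflow *Q<sub>s</sub>* flushes the
headspace and the net interfacial flux is

> *J = (K<sub>hl</sub> C<sub>l</sub> − C<sub>h</sub>) k<sub>glob</sub>*,
> with 1/*k<sub>glob</sub>* = 1/*k<sub>h</sub>* + *K<sub>hl</sub>*/*k<sub>l</sub>*

(*k<sub>h</sub>*, *k<sub>l</sub>*: headspace- and liquid-side transfer
coefficients). The resulting three-compartment ODE system (liquid,
headspace, transport tube) is integrated in dimensionless form. Shortly
after valve opening, and as long as liquid depletion is negligible, the
headspace settles at the **dynamic pseudo-stationary regime**

> *Y<sub>h,psr</sub> = A / (A + Q<sub>s</sub>/k<sub>glob</sub>)*

— a fraction of the equilibrium headspace concentration that depends only
on the device and on *K<sub>hl</sub>*. The package provides:

- unit handling and Henry/ideal-gas conversions (v/v dilution → mol/m³ →
  ppbv), bottle-loading mass balance (`dilution_to_liquid_molar`,
  `molar_to_ppbv`, `bottle_loading`);
- the compartment simulator and pseudo-stationary analytics
  (`simulate_device`, `psr`, `delivered_plateau`,
  `stimulus_shape_summary`);
- Reynolds/Schmidt/Sherwood prediction of *k<sub>h</sub>* from source
  geometry and airflow (`reynolds`, `kh_from_correlation`,
  `predicted_psr_surface`);
- calibration of (*k<sub>h</sub>*, *k<sub>l</sub>*) from PID plateau
  measurements by log-parametrised nonlinear least squares
  (`extract_plateau`, `pid_calibration_curve`, `flow_correction`,
  `fit_transfer_coefficients`);
- partition-coefficient estimation from headspace GC-FID data by the
  phase-ratio-variation and liquid-calibration methods (`prv_fit`,
  `lc_fit`);
- source lifetime and design-space sweeps over diameter and airflow
  (`source_lifetime`, `lifetime_quasi_steady`, `design_sweep`);
- seeded synthetic generators for every measurement type, so all fitting
  paths are testable without instruments (`gen_plateau_observations`,
  `gen_pid_trace`, `gen_prv_series`, `gen_lc_series`).

A measured panel of 11 volatile plant compounds (air–mineral oil
*K<sub>hl</sub>* spanning six orders of magnitude) and the reference
device description ship as plain-text fixtures
(`odorcal_example("vpc_panel.csv")`,
`odorcal_example("reference_device.yaml")`).

## Worked example

Predict what a 0.1% v/v (Z)-3-hexenyl acetate (Z3HA) source delivers from
the reference device:

```r
library(odorcal)
cfg   <- read_device_config(odorcal_example("reference_device.yaml"))
panel <- read_compound_table(odorcal_example("vpc_panel.csv"))
z3ha  <- panel[["(Z)-3-hexenyl acetate"]]

psr(cfg$device, cfg$transfer, z3ha)
#> [1] 0.3171383

c_l0 <- dilution_to_liquid_molar(1e-3, z3ha)   # 0.1% v/v -> 6.31 mol/m^3
out  <- delivered_plateau(cfg$device, cfg$transfer, z3ha, c_l0)
molar_to_ppbv(out$c_c_psr)
#> [1] 164.128

source_lifetime(cfg$device, cfg$transfer, z3ha)
#> <lifetime_result> 29.9 min (method = ode, Y_h,psr = 0.317)
```

Read: the headspace stabilises at 32% of its equilibrium concentration;
after the 8-fold carrier dilution the tube outlet carries ≈160 ppbv; the
source keeps delivering within 5% of that plateau for about half an hour.

A command-line wrapper with subcommands `simulate`, `psr`, `calibrate`,
`khl prv|lc`, `lifetime`, `design` and `synth` is installed under
`inst/exec/odorcal` (see `odorcal_cli()`).

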