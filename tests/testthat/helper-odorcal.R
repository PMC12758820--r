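# Shared fixtures, built in code.

ref_dev <- reference_device()
ref_k <- reference_transfer()

# Partition coefficients of the measured compound panel (air-mineral oil),
# spanning six orders of magnitude.
panel_khl <- c(
  isoprene = 1.14e-2, ethyl_acetate = 6.98e-3, pentanal = 2.54e-3,
  z3_hexenol = 7.49e-4, e2_hexenal = 6.25e-4, alpha_pinene = 3.84e-5,
  z3ha = 2.71e-5, eucalyptol = 1.49e-5, linalool = 7.48e-6,
  indole = 1.88e-6, beta_caryophyllene = 1.92e-7
)

# The nine compounds for which a stationary plateau is observable within a
# one-minute stimulation (the two least volatile never stabilise).
panel_khl_obs <- panel_khl[1:9]

z3ha_compound <- compound("Z3HA", khl = 2.71e-5, khl_ci = c(2.70e-5, 2.72e-5),
                          mw = 142.2, density = 0.897)
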