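# The 8-valve vial stimulator used in the package's worked examples:
# a 4-mL vial (13.2 mm inner diameter, measured interface area 1.38 cm^2)
# holding 1 mL of odorant solution under 3 mL of headspace, flushed at
# 200 mL/min during stimulation; all 8 lines merge into a 200 mm x 9 mm
# glass tube carrying 1600 mL/min in total.
device:
  d_mm: 13.2
  area_cm2: 1.38
  v_l_ml: 1.0
  v_h_ml: 3.0
  v_c_ml: 12.72
  q_s_ml_min: 200
  q_c_ml_min: 1600
# Transfer coefficients calibrated on this device from plateau
# observations of a volatile-compound panel.
transfer:
  k_h: 1.15e-2
  k_l: 1.24e-5
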