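# Representative electrochemical drug-delivery device ("table2" preset).
# Units: mm / um / MPa / mPa_s / mA / K / kPa, converted to SI on ingest.
device:
  R0_mm: 1.2
  h_um: 150
  E_MPa: 8
  v: 0.5
  a_um: 50
  b_um: 50
  L_mm: 20
  mu_mPa_s: 0.89
operating:
  i_mA: 0.5
  T_K: 310
  P0_kPa: 101.325
  V0star: 0.9162
solver:
  rtol: 1.0e-8
  atol: 1.0e-12
  n_intervals: 10000
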