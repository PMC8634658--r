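name: CGXII
carbon_source: EX_glc__D_e
components:
  EX_glc__D_e: 10
  EX_nh4_e: 10
  EX_so4_e: 10
  EX_k_e: 10
  EX_pi_e: 10
  EX_na1_e: 10
  EX_mg2_e: 10
  EX_ca2_e: 10
  EX_fe2_e: 10
  EX_mn2_e: 10
  EX_zn2_e: 10
  EX_cu2_e: 10
  EX_ni2_e: 10
  EX_cl_e: 10
  EX_btn_e: 10
  EX_34dhbz_e: 10
  EX_h2o_e: 10
  EX_h_e: 10
  EX_o2_e: 10
notes: >-
  Chemically defined minimal medium for C. glutamicum (Keilhauer
  composition) encoded as BiGG exchange identifiers, including biotin and
  protocatechuate. Uniform uptake magnitude of 10 mmol/gDW/h for every
  component; oxygen uptake is governed by the aerobic flag.
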