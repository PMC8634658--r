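name: M9
carbon_source: EX_glc__D_e
components:
  EX_glc__D_e: 10
  EX_nh4_e: 10
  EX_pi_e: 10
  EX_k_e: 10
  EX_na1_e: 10
  EX_cl_e: 10
  EX_so4_e: 10
  EX_mg2_e: 10
  EX_ca2_e: 10
  EX_fe2_e: 10
  EX_ni2_e: 10
  EX_h2o_e: 10
  EX_h_e: 10
  EX_o2_e: 10
notes: >-
  Generic minimal medium (Sambrook composition) as BiGG exchange
  identifiers, extended with nickel and calcium which corynebacterial
  models require for growth. Uniform uptake magnitude 10 mmol/gDW/h.
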