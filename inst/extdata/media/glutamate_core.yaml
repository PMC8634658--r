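name: glutamate core minimal
carbon_source: EX_glc__D_e
components:
  EX_glc__D_e: 10
  EX_nh4_e: 10
  EX_pi_e: 10
  EX_h_e: 1000
  EX_h2o_e: 1000
  EX_o2_e: 1000
notes: >-
  Native medium of the synthetic glutamate-core model: glucose-limited
  (10 mmol/gDW/h), nitrogen and phosphate at the default magnitude,
  protons and water freely exchanged, oxygen in excess so that carbon --
  not aeration -- limits the hand-derived optima.
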