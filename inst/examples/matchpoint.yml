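# Theoretical contrast match point of beta-chitin
# (anhydro-GlcNAc repeat unit, full labile exchange).
composition:
  formula: C8H13NO5
  labile_h: 3
  density: 1.5
  exchange_fraction: 1.0
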