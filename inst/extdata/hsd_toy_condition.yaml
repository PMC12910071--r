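# Example condition specification for the toy model: a high-sugar-diet-like
# state encoded as tightened uptake and dehydrogenase bounds. The magnitudes
# are placeholders illustrating the schema, not measured values.
bound_overrides:
  - reaction: EX_glc
    upper: 5
  - reaction: GAPDH
    upper: 1
directionality:
  - reaction: NOXc
    direction: forward_only
undetected_exchange_scale: 0.1
detected_metabolites:
  - glc[c]
  - biomass[c]
notes: "placeholder toy constraints; see the condition_builder docs"
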