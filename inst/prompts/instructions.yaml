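# Instruction templates for prefix-conditioned decoding, one per caption
# field. "{field}" is substituted by the field name.
default: "predict {field}"
fields:
  chromosome: "predict chromosome"
  variant_type: "predict variant_type"
  consequence: "predict consequence"
  nearest_genes: "predict nearest_genes"
  cell_types: "predict cell_types"
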