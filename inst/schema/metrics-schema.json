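{
  "name": "ectishape-metrics",
  "version": 1,
  "description": "Per-site interface metrics record",
  "required": {
    "schema": "string",
    "l_um": "number",
    "L_um": "number",
    "delta_L_um": "number",
    "delta_L_norm": "number",
    "parameters": "object"
  },
  "optional": {
    "seed": "number",
    "thickness_um": "number",
    "nuclear_density_per_100um2": "number"
  }
}
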