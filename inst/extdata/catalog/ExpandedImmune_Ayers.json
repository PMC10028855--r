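{
  "name": "ExpandedImmune_Ayers",
  "topic": "Immune system status",
  "tumor_types": "pan-cancer",
  "first_author": "Ayers",
  "reference_id": "60",
  "input_types": "sequencing",
  "required_scale": "log",
  "method": "zscore_mean",
  "genes": {
    "symbol": []
  },
  "centroids": null,
  "genes_available": false,
  "genes_synthetic": false
}
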