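{
  "name": "CIN_Carter",
  "topic": "Chromosomal instability",
  "tumor_types": "pan-cancer",
  "first_author": "Carter",
  "reference_id": "46",
  "input_types": ["microarray", "sequencing"],
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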