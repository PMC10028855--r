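{
  "name": "Chemokines_Messina",
  "topic": "Immune system status",
  "tumor_types": "pan-cancer",
  "first_author": "Messina",
  "reference_id": "42",
  "input_types": ["microarray", "sequencing"],
  "required_scale": "log",
  "method": "zscore_mean",
  "genes": {
    "symbol": ["CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18", "CCL19", "CCL21", "CXCL9", "CXCL10", "CXCL11", "CXCL13"]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": false
}
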