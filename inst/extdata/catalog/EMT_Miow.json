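{
  "name": "EMT_Miow",
  "topic": "Epithelial to mesenchymal transition rate",
  "tumor_types": "ovarian cancer",
  "first_author": "Miow",
  "reference_id": "31",
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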