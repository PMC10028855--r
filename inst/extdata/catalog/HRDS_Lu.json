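{
  "name": "HRDS_Lu",
  "topic": "Chromosomal instability",
  "tumor_types": ["ovarian cancer", "breast cancer"],
  "first_author": "Lu",
  "reference_id": "68",
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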