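{
  "name": "Autophagy_Wang",
  "topic": "Autophagy activity",
  "tumor_types": "glioblastoma",
  "first_author": "Wang",
  "reference_id": "65",
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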