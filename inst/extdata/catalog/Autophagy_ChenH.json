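{
  "name": "Autophagy_ChenH",
  "topic": "Autophagy activity",
  "tumor_types": "cervical cancer",
  "first_author": "Chen H",
  "reference_id": "66",
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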