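{
  "name": "Ferroptosis_Liu",
  "topic": "Ferroptosis activity",
  "tumor_types": "prostate cancer",
  "first_author": "Liu",
  "reference_id": "75",
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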