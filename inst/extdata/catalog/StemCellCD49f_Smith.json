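{
  "name": "StemCellCD49f_Smith",
  "topic": "Stemness status",
  "tumor_types": "prostate cancer",
  "first_author": "Smith",
  "reference_id": "32",
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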