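{
  "name": "Glycolysis_Xu",
  "topic": "Tumor metabolisms",
  "tumor_types": "renal cell carcinoma",
  "first_author": "Xu",
  "reference_id": "86",
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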