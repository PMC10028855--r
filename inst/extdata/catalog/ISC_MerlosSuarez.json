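{
  "name": "ISC_MerlosSuarez",
  "topic": "Stemness status",
  "tumor_types": "colorectal cancer",
  "first_author": "Merlos-Suarez",
  "reference_id": "91",
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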