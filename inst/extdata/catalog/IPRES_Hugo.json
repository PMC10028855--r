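{
  "name": "IPRES_Hugo",
  "topic": "Immune system status",
  "tumor_types": "metastatic melanoma",
  "first_author": "Hugo",
  "reference_id": "82",
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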