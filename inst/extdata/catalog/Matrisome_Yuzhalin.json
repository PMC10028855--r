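{
  "name": "Matrisome_Yuzhalin",
  "topic": "Extracellular matrix composition",
  "tumor_types": ["ovarian cystadenocarcinoma", "gastric adenocarcinoma", "colorectal adenocarcinoma", "lung adenocarcinoma"],
  "first_author": "Yuzhalin",
  "reference_id": "71",
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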