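{
  "name": "IFN_Ayers",
  "topic": "Immune system status",
  "tumor_types": "pan-cancer",
  "first_author": "Ayers",
  "reference_id": "60",
  "input_types": "sequencing",
  "required_scale": "log",
  "method": "ssgsea",
  "genes": {
    "symbol": ["IFNG", "STAT1", "IDO1", "CXCL10", "CXCL9", "HLA-DRA"]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": false
}
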