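{
  "name": "ECM_Chakravarthy",
  "topic": "Extracellular matrix composition",
  "tumor_types": "pan-cancer",
  "first_author": "Chakravarthy",
  "reference_id": "40",
  "input_types": "sequencing",
  "required_scale": "log",
  "method": "up_down_diff",
  "genes": {
    "symbol": ["COL1A1", "COL5A1", "COL10A1", "COL11A1", "FN1", "POSTN", "THBS2", "SPARC", "LOX", "SULF1", "CTHRC1", "INHBA", "MMP11", "FAP", "VCAN", "DCN", "LUM", "OGN", "ABCA8", "CILP", "FBLN5", "PCOLCE2", "SCARA5", "CHRDL1", "GSN", "MFAP4", "ADH1B", "C7", "PI16", "ANGPTL1"],
    "direction": ["up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down"]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": true
}
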