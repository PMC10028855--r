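{
  "name": "ConsensusOV_Chen",
  "topic": "Tumor subtypes",
  "tumor_types": "high-grade serous ovarian carcinoma",
  "first_author": "Chen",
  "reference_id": "30",
  "input_types": ["microarray", "sequencing"],
  "required_scale": "log",
  "method": "consensus_centroid",
  "genes": {
    "symbol": ["CXCL9", "CXCL10", "CXCL11", "CXCL13", "IDO1", "GZMB", "PRF1", "CD38", "TAP1", "PSMB9", "MUC16", "MUC1", "SLPI", "CD24", "KRT18", "WFDC2", "S100A4", "CLDN3", "EPCAM", "MSLN", "MCM2", "PCNA", "CDC20", "TOP2A", "BUB1", "CCNB1", "MKI67", "AURKA", "PLK1", "FOXM1", "FAP", "POSTN", "THBS2", "COL5A1", "COL11A1", "ZEB1", "VIM", "FN1", "SPARC", "LOX"]
  },
  "centroids": {
    "genes": ["CXCL9", "CXCL10", "CXCL11", "CXCL13", "IDO1", "GZMB", "PRF1", "CD38", "TAP1", "PSMB9", "MUC16", "MUC1", "SLPI", "CD24", "KRT18", "WFDC2", "S100A4", "CLDN3", "EPCAM", "MSLN", "MCM2", "PCNA", "CDC20", "TOP2A", "BUB1", "CCNB1", "MKI67", "AURKA", "PLK1", "FOXM1", "FAP", "POSTN", "THBS2", "COL5A1", "COL11A1", "ZEB1", "VIM", "FN1", "SPARC", "LOX"],
    "subtypes": ["DIF", "IMR", "MES", "PRO"],
    "values": [
      [-0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5],
      [2, 2, 2, 2, 2, 2, 2, 2, 2, 2, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5],
      [-0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2],
      [-0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5]
    ]
  },
  "genes_available": true,
  "genes_synthetic": true
}
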