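{
  "name": "EMT_Cheng",
  "topic": "Epithelial to mesenchymal transition rate",
  "tumor_types": "breast cancer",
  "first_author": "Cheng",
  "reference_id": "61",
  "input_types": ["microarray", "sequencing"],
  "required_scale": "log",
  "method": "weighted_sum",
  "genes": {
    "symbol": ["CDH2", "VIM", "FN1", "SNAI1", "SNAI2", "TWIST1", "TWIST2", "ZEB1", "ZEB2", "MMP2", "MMP3", "MMP9", "ITGB1", "ITGA5", "COL1A1", "COL1A2", "COL3A1", "COL5A2", "SPARC", "TNC", "POSTN", "FBN1", "TGFB1", "TGFB2", "TGFBI", "WNT5A", "WNT5B", "SERPINE1", "TIMP1", "LAMC2", "CDH1", "SDC1", "KRT8", "KRT18", "KRT19", "DSP", "OCLN", "CLDN3", "CLDN4", "CLDN7", "EPCAM", "MUC1", "ESRP1", "ESRP2", "GRHL2", "OVOL2", "CRB3", "TJP1", "ST14", "RAB25", "MARVELD3"],
    "direction": ["up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down", "down"],
    "weight": [0.657, 1.425, 0.66, 0.221, 0.255, 0.405, 1.028, 0.298, 0.308, 0.573, 0.753, 0.543, 1.187, 0.834, 1.105, 0.715, 1.39, 0.354, 0.688, 0.708, 0.331, 1.01, 0.297, 0.297, 1.093, 0.612, 1.467, 1.199, 0.33, 0.689, -0.277, -1.443, -1.036, -1.441, -1.224, -1.223, -1.146, -0.33, -0.439, -0.232, -0.919, -1.029, -0.699, -0.868, -0.578, -1.492, -1.281, -0.821, -0.95, -1.114, -1.241]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": true
}
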