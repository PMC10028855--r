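{
  "name": "IPS_Charoentong",
  "topic": "Immune system status",
  "tumor_types": "pan-cancer",
  "first_author": "Charoentong",
  "reference_id": "78",
  "input_types": "sequencing",
  "required_scale": "log",
  "method": "ips_composite",
  "genes": {
    "symbol": ["CD40LG", "CD69", "ICOS", "GZMA", "GZMB", "PRF1", "CCR2", "IL7R", "LTB", "EOMES", "CXCR3", "KLRG1", "FOXP3", "IL2RA", "IKZF2", "ARG1", "NOS2", "CD14", "HLA-A", "HLA-B", "HLA-C", "HLA-DPA1", "HLA-DPB1", "HLA-E", "HLA-F", "B2M", "TAP1", "TAP2", "PDCD1", "CTLA4", "LAG3", "TIGIT", "CD274", "PDCD1LG2", "HAVCR2", "IDO1", "BTLA", "VTCN1"],
    "weight": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1, -1, -1, -1, -1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1],
    "class_label": ["EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "SC", "SC", "SC", "SC", "SC", "SC", "MHC", "MHC", "MHC", "MHC", "MHC", "MHC", "MHC", "MHC", "MHC", "MHC", "CP", "CP", "CP", "CP", "CP", "CP", "CP", "CP", "CP", "CP"],
    "subclass": ["Act_CD4", "Act_CD4", "Act_CD4", "Act_CD8", "Act_CD8", "Act_CD8", "Tem_CD4", "Tem_CD4", "Tem_CD4", "Tem_CD8", "Tem_CD8", "Tem_CD8", "Treg", "Treg", "Treg", "MDSC", "MDSC", "MDSC", "HLA-A", "HLA-B", "HLA-C", "HLA-DPA1", "HLA-DPB1", "HLA-E", "HLA-F", "B2M", "TAP1", "TAP2", "PDCD1", "CTLA4", "LAG3", "TIGIT", "CD274", "PDCD1LG2", "HAVCR2", "IDO1", "BTLA", "VTCN1"]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": true
}
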