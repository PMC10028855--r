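{
  "name": "Hypoxia_Buffa",
  "topic": "Hypoxia activity",
  "tumor_types": "pan-cancer",
  "first_author": "Buffa",
  "reference_id": "38",
  "input_types": ["microarray", "sequencing"],
  "required_scale": "log",
  "method": "zscore_mean",
  "genes": {
    "symbol": ["VEGFA", "SLC2A1", "PGAM1", "ENO1", "LDHA", "TPI1", "P4HA1", "MRPS17", "CDKN3", "ADM", "NDRG1", "TUBB6", "ALDOA", "MIF", "ACOT7", "MCTS1", "PSRC1", "PSMA7", "ANLN", "SLC25A32", "SHCBP1", "CTSL", "KIF20A", "GAPDH", "CHCHD2", "VPS37A", "SEC61G", "CORO1C", "GPI", "ANKRD37", "PFKP", "BNIP3", "PGK1", "CA9", "HK2", "DDIT4", "EGLN3", "PDK1", "AK4", "CD109", "HILPDA", "MAFF", "MXI1", "SLC16A1", "STC2", "ERO1A", "FAM162A", "GBE1", "PPP1R3C", "UPK1A", "KDELR3", "IGFBP3"]
  },
  "centroids": null,
  "genes_available": true,
  "genes_synthetic": true
}
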