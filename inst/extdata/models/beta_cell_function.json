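{
  "model_name": "beta_cell_function",
  "slices": [
    {
      "slice_name": "ACHE",
      "assay_ids": ["ACHE_1", "ACHE_2"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "BCHE",
      "assay_ids": ["BCHE_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "DRD",
      "assay_ids": ["DRD1_1", "DRD2_1", "DRD3_1", "DRD5_1", "OPRD1_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "DRD_SLC",
      "assay_ids": ["SLC6A3_1", "SLC6A3_2"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "ESR1",
      "assay_ids": ["ESR1_1", "ESR1_2", "ESR1_3", "ESR1_4"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "GABA",
      "assay_ids": ["GABRA1_1", "GABRA2_1", "GABRA3_1", "GABRB1_1", "GABRG2_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "HTR",
      "assay_ids": ["HTR1A_1", "HTR2A_1", "HTR2C_1", "HTR3A_1", "HTR4_1", "HTR5A_1", "HTR6_1", "HTR7_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "HTR_SLC",
      "assay_ids": ["SLC6A4_1", "SLC6A4_2"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "INSR",
      "assay_ids": ["INSR_1", "INSR_2"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "KCNJ11",
      "assay_ids": ["KCNJ11_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "PPARa",
      "assay_ids": ["PPARA_1", "PPARA_2"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "PPARd",
      "assay_ids": ["PPARD_1"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "PPARg",
      "assay_ids": ["PPARG_1", "PPARG_2", "PPARG_3", "PPARG_4"],
      "weight": 0.0714285714285714
    },
    {
      "slice_name": "PPRE",
      "assay_ids": ["PPRE_1"],
      "weight": 0.0714285714285714
    }
  ]
}
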