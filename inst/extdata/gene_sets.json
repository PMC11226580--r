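{
  "table2": {
    "glycolysis": ["GCK", "HK1", "HK2", "GPI", "PFKM", "ALDOA", "ALDOC", "TPI1", "GAPDH", "PGAM2", "ENO1", "ENO2", "ENO3", "PKM"],
    "citric_acid_cycle": ["CS", "ACO2", "IDH1", "IDH2", "IDH3B", "IDH3G", "DLD", "SUCLG1", "SUCLG2", "SDHA", "SDHB", "FH", "MDH2"],
    "pentose_phosphate": ["G6PD", "PGLS", "PGD", "TKT"],
    "citrate_shuttle": ["CS", "SLC25A1", "ACLY", "MDH2", "ME1", "ME2", "MPC2"],
    "fatty_acid_synthesis": ["ACACA", "ACSL1", "ACSL3", "ACSL4", "ELOVL1", "ELOVL5", "ELOVL6", "HACD2", "TECR", "SCD", "SCD5"],
    "carnitine_shuttle": [],
    "fatty_acid_oxidation": ["ACADM", "ACADVL", "ACAD9", "HADH", "HADHA", "HADHB"]
  },
  "table4_liver": {
    "glycolysis": ["GCK", "PKLR"],
    "citric_acid_cycle": ["ACO2"],
    "pentose_phosphate": ["ME1", "MTHFD2"],
    "citrate_shuttle": ["ACLY", "ME1"],
    "fatty_acid_synthesis": ["ACACB", "ELOVL5", "SCD", "ACSL3"],
    "carnitine_shuttle": [],
    "fatty_acid_oxidation": ["CD36", "ACOT2", "HADHB", "VLDLR"]
  },
  "table4_adipose": {
    "glycolysis": ["LDHA", "PFKM", "SLC2A4"],
    "citric_acid_cycle": ["ACO2", "IDH3A", "MDH2"],
    "pentose_phosphate": [],
    "citrate_shuttle": ["ACLY", "MDH1", "PC"],
    "fatty_acid_synthesis": ["ACACA", "ELOVL6", "SCD", "HSD17B12", "LIPE", "MGLL"],
    "carnitine_shuttle": [],
    "fatty_acid_oxidation": ["APOBR", "ACAA2", "ACSF2"]
  },
  "table4_muscle": {
    "glycolysis": ["LDHB"],
    "citric_acid_cycle": [],
    "pentose_phosphate": [],
    "citrate_shuttle": [],
    "fatty_acid_synthesis": ["ELOVL6", "ACSL1"],
    "carnitine_shuttle": ["CPT1B"],
    "fatty_acid_oxidation": ["CD36", "LIPE", "LPL"]
  },
  "table6": {
    "glycolysis": ["GPI", "ALDOC", "TPI1", "PGK1", "PGAM1", "ENO1", "ENO2", "ENO3", "PKLR", "PKM"],
    "citric_acid_cycle": ["CS", "ACO2", "IDH1", "IDH2", "IDH3A", "OGDH", "DLD", "DLST", "SUCLG1", "SUCLA2", "SUCLG2", "SDHA", "SDHB", "SDHD", "MDH2"],
    "pentose_phosphate": ["G6PD", "PGLS", "PGD", "RPE", "RPIA", "TKT", "TALDO1"],
    "citrate_shuttle": ["CS", "ACLY", "MDH2", "MPC1", "PC"],
    "fatty_acid_synthesis": ["ACACA", "FASN", "ACSL1", "ACSL3", "ACSL4", "ACSL5", "ELOVL1", "ELOVL2", "ELOVL5", "HACD2", "HACD3"],
    "carnitine_shuttle": ["SLC25A20", "CPT2"],
    "fatty_acid_oxidation": ["ACADM", "ECHS1"]
  },
  "table3_regulators": {
    "regulators": ["BRCA1", "MID1IP1", "ACACB", "CD36", "LDLR", "VLDLR", "FGF21", "GDF15"]
  }
}
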