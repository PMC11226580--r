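gene	tissue	fold_change	p_value	pathway
GCK	liver	0.55	9E-04	glycolysis
PKLR	liver	0.62	2E-03	glycolysis
LDHA	adipose	1.74	2E-03	glycolysis
PFKM	adipose	1.65	4E-02	glycolysis
SLC2A4	adipose	1.89	8E-04	glycolysis
LDHB	muscle	2.58	3E-02	glycolysis
ACO2	liver	1.57	3E-07	citric_acid_cycle
ACO2	adipose	1.56	9E-04	citric_acid_cycle
IDH3A	adipose	1.76	1E-04	citric_acid_cycle
MDH2	adipose	1.57	3E-04	citric_acid_cycle
ME1	liver	1.70	6E-03	pentose_phosphate
MTHFD2	liver	4.54	1E-06	pentose_phosphate
ACLY	liver	0.48	1E-03	citrate_shuttle
ACLY	adipose	1.68	1E-02	citrate_shuttle
MDH1	adipose	1.57	9E-04	citrate_shuttle
PC	adipose	1.71	1E-03	citrate_shuttle
ACACB	liver	0.46	2E-07	fatty_acid_synthesis
ELOVL5	liver	0.65	3E-05	fatty_acid_synthesis
SCD	liver	0.07	5E-06	fatty_acid_synthesis
ACSL3	liver	0.58	7E-03	fatty_acid_synthesis
ACACA	adipose	3.35	3E-06	fatty_acid_synthesis
ELOVL6	adipose	4.04	3E-05	fatty_acid_synthesis
SCD	adipose	2.66	2E-04	fatty_acid_synthesis
HSD17B12	adipose	1.79	5E-05	fatty_acid_synthesis
LIPE	adipose	1.71	1E-02	fatty_acid_synthesis
MGLL	adipose	1.61	2E-02	fatty_acid_synthesis
ELOVL6	muscle	2.04	5E-02	fatty_acid_synthesis
ACSL1	muscle	1.72	4E-03	fatty_acid_synthesis
CPT1B	muscle	1.80	1E-03	carnitine_shuttle
CD36	liver	1.78	6E-04	fatty_acid_oxidation
ACOT2	liver	1.66	1E-05	fatty_acid_oxidation
HADHB	liver	1.62	5E-04	fatty_acid_oxidation
VLDLR	liver	5.79	2E-09	fatty_acid_oxidation
APOBR	adipose	0.62	1E-02	fatty_acid_oxidation
ACAA2	adipose	1.55	1E-02	fatty_acid_oxidation
ACSF2	adipose	1.52	4E-03	fatty_acid_oxidation
CD36	muscle	1.71	3E-02	fatty_acid_oxidation
LIPE	muscle	1.68	6E-03	fatty_acid_oxidation
LPL	muscle	1.75	2E-02	fatty_acid_oxidation
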