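metabolite	tissue	fold_change	significant	group
Glucose	liver	0.80	TRUE	glycolytic_intermediates
Glucose	adipose	0.72	FALSE	glycolytic_intermediates
Glucose	muscle	1.14	FALSE	glycolytic_intermediates
Glucose	serum	0.79	FALSE	glycolytic_intermediates
Glucose-6P	adipose	1.02	FALSE	glycolytic_intermediates
Glucose-6P	muscle	4.10	FALSE	glycolytic_intermediates
3P-Glycerate	liver	0.69	TRUE	glycolytic_intermediates
3P-Glycerate	adipose	1.35	FALSE	glycolytic_intermediates
3P-Glycerate	muscle	1.20	FALSE	glycolytic_intermediates
PEP	liver	0.65	TRUE	glycolytic_intermediates
PEP	adipose	2.80	FALSE	glycolytic_intermediates
PEP	muscle	1.16	FALSE	glycolytic_intermediates
Pyruvate	liver	0.43	TRUE	glycolytic_intermediates
Pyruvate	muscle	1.11	FALSE	glycolytic_intermediates
Pyruvate	serum	0.24	TRUE	glycolytic_intermediates
Lactate	liver	0.70	TRUE	glycolytic_intermediates
Lactate	adipose	0.88	FALSE	glycolytic_intermediates
Lactate	muscle	0.96	FALSE	glycolytic_intermediates
Lactate	serum	0.89	FALSE	glycolytic_intermediates
L/P ratio	liver	1.63	TRUE	glycolytic_intermediates
L/P ratio	muscle	0.86	FALSE	glycolytic_intermediates
L/P ratio	serum	3.71	TRUE	glycolytic_intermediates
Citrate	adipose	0.58	FALSE	citric_acid_cycle_intermediates
Citrate	muscle	0.53	TRUE	citric_acid_cycle_intermediates
Citrate	serum	1.26	TRUE	citric_acid_cycle_intermediates
Succinate	liver	1.61	FALSE	citric_acid_cycle_intermediates
Succinate	adipose	0.72	FALSE	citric_acid_cycle_intermediates
Succinate	serum	0.90	FALSE	citric_acid_cycle_intermediates
Fumarate	liver	0.88	FALSE	citric_acid_cycle_intermediates
Fumarate	adipose	1.29	FALSE	citric_acid_cycle_intermediates
Fumarate	muscle	1.05	FALSE	citric_acid_cycle_intermediates
Fumarate	serum	0.78	FALSE	citric_acid_cycle_intermediates
Malate	liver	0.89	FALSE	citric_acid_cycle_intermediates
Malate	adipose	1.13	FALSE	citric_acid_cycle_intermediates
Malate	muscle	1.44	FALSE	citric_acid_cycle_intermediates
Malate	serum	0.96	FALSE	citric_acid_cycle_intermediates
6P-Gluconate	liver	1.88	TRUE	pentose_phosphate_intermediates
6P-Gluconate	adipose	1.42	FALSE	pentose_phosphate_intermediates
Palmitate	liver	0.85	FALSE	fatty_acids
Palmitate	adipose	1.38	FALSE	fatty_acids
Palmitate	muscle	0.93	FALSE	fatty_acids
Palmitate	serum	1.19	FALSE	fatty_acids
Palmitoleate	liver	0.52	TRUE	fatty_acids
Palmitoleate	adipose	2.37	TRUE	fatty_acids
Palmitoleate	muscle	0.91	FALSE	fatty_acids
Palmitoleate	serum	1.46	FALSE	fatty_acids
Stearate	liver	0.88	TRUE	fatty_acids
Stearate	muscle	1.06	FALSE	fatty_acids
Stearate	serum	1.10	FALSE	fatty_acids
Oleate	liver	0.73	FALSE	fatty_acids
Oleate	adipose	2.60	TRUE	fatty_acids
Oleate	muscle	0.76	FALSE	fatty_acids
Oleate	serum	1.17	FALSE	fatty_acids
Linoleate	liver	1.01	FALSE	fatty_acids
Linoleate	adipose	1.57	FALSE	fatty_acids
Linoleate	muscle	0.83	FALSE	fatty_acids
Linoleate	serum	1.29	FALSE	fatty_acids
Linolenate	liver	1.87	FALSE	fatty_acids
Linolenate	adipose	1.47	FALSE	fatty_acids
Linolenate	muscle	0.75	FALSE	fatty_acids
Linolenate	serum	1.52	FALSE	fatty_acids
Arachidonate	liver	1.03	FALSE	fatty_acids
Arachidonate	adipose	1.40	FALSE	fatty_acids
Arachidonate	muscle	0.71	FALSE	fatty_acids
Arachidonate	serum	0.97	FALSE	fatty_acids
Docosahexaenoate	liver	0.80	FALSE	fatty_acids
Docosahexaenoate	adipose	2.94	TRUE	fatty_acids
Docosahexaenoate	muscle	1.78	FALSE	fatty_acids
Docosahexaenoate	serum	1.13	FALSE	fatty_acids
beta-Hydroxybutyrate	liver	1.17	FALSE	ketone_bodies
beta-Hydroxybutyrate	muscle	3.22	TRUE	ketone_bodies
beta-Hydroxybutyrate	serum	2.44	TRUE	ketone_bodies
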