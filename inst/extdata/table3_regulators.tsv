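gene	condition	fold_change	p_value	p_censored	significant	low_expression	mode_of_action
BRCA1	mpp	0.29	1E-10	FALSE	TRUE	TRUE	Inhibition of ACACA
BRCA1	metformin	0.16	2E-56	FALSE	TRUE	FALSE	Inhibition of ACACA
MID1IP1	mpp	5.30	1E-67	FALSE	TRUE	FALSE	Activation of ACACA
MID1IP1	metformin	2.15	5E-87	FALSE	TRUE	FALSE	Activation of ACACA
ACACB	mpp	1.77	5E-08	FALSE	TRUE	TRUE	Inhibition of beta-oxidation
ACACB	metr_liver	0.32	1E-03	TRUE	TRUE	FALSE	Inhibition of beta-oxidation
ACACB	metr_adipose	0.86	0.7	FALSE	FALSE	FALSE	Inhibition of beta-oxidation
ACACB	metformin	0.30	7E-34	FALSE	TRUE	FALSE	Inhibition of beta-oxidation
CD36	mpp	0.71	0.7	FALSE	FALSE	TRUE	Fatty acid uptake
CD36	metr_liver	8.30	1E-03	TRUE	TRUE	FALSE	Fatty acid uptake
CD36	metformin	0.56	0.02	FALSE	FALSE	TRUE	Fatty acid uptake
LDLR	mpp	5.33	1E-99	TRUE	TRUE	FALSE	Cholesterol and lipid uptake
LDLR	metformin	2.89	1E-99	TRUE	TRUE	FALSE	Cholesterol and lipid uptake
VLDLR	mpp	1.17	0.1	FALSE	FALSE	FALSE	Triglyceride uptake
VLDLR	metr_liver	92.78	1E-03	TRUE	TRUE	FALSE	Triglyceride uptake
VLDLR	metformin	0.43	1E-23	FALSE	TRUE	TRUE	Triglyceride uptake
FGF21	mpp	57.74	2E-04	FALSE	FALSE	TRUE	Induction of lipolysis
FGF21	metr_liver	16.07	1E-03	TRUE	TRUE	FALSE	Induction of lipolysis
FGF21	metr_adipose	1.84	0.003	FALSE	TRUE	FALSE	Induction of lipolysis
FGF21	metformin	5.61	0.2	FALSE	FALSE	TRUE	Induction of lipolysis
GDF15	mpp	7.42	7E-11	FALSE	TRUE	TRUE	Induction of lipolysis
GDF15	metformin	9.65	1E-99	TRUE	TRUE	FALSE	Induction of lipolysis
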