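gene	fold_change	p_value	baseline_rpkm	pathway	gene_name
GPI	0.71	4E-26	51	glycolysis	Glucose-6-phosphate isomerase
ALDOC	0.43	4E-11	564	glycolysis	Fructose-bisphosphate aldolase C
TPI1	0.61	6E-63	400	glycolysis	Triosephosphate isomerase 1
PGK1	0.73	2E-23	179	glycolysis	Phosphoglycerate kinase 1
PGAM1	0.46	2E-87	90	glycolysis	Phosphoglycerate mutase 1
ENO1	0.64	3E-57	760	glycolysis	Enolase 1
ENO2	0.55	2E-46	27	glycolysis	Enolase 2
ENO3	0.55	2E-19	9	glycolysis	Enolase 3
PKLR	0.61	2E-30	23	glycolysis	Pyruvate kinase, liver
PKM	0.61	2E-62	167	glycolysis	Pyruvate kinase M1/2
CS	1.18	5E-07	45	citric_acid_cycle	Citrate synthase
ACO2	1.60	3E-39	10	citric_acid_cycle	Aconitase 2
IDH1	0.62	1E-70	119	citric_acid_cycle	Isocitrate dehydrogenase 1 (NADP+)
IDH2	0.82	3E-08	47	citric_acid_cycle	Isocitrate dehydrogenase 2 (NADP+)
IDH3A	1.52	5E-13	4	citric_acid_cycle	Isocitrate dehydrogenase 3 alpha
OGDH	1.33	3E-09	10	citric_acid_cycle	Oxoglutarate dehydrogenase
DLD	1.49	1E-14	8	citric_acid_cycle	Dihydrolipoamide dehydrogenase
DLST	1.62	7E-42	20	citric_acid_cycle	Dihydrolipoamide S-succinyltransferase
SUCLG1	1.35	8E-11	15	citric_acid_cycle	Succinate-CoA ligase subunit alpha
SUCLA2	1.58	2E-16	4	citric_acid_cycle	Succinate-CoA ligase [ADP-forming] subunit beta
SUCLG2	1.29	1E-06	14	citric_acid_cycle	Succinate-CoA ligase [GDP-forming] subunit beta
SDHA	1.47	8E-13	4	citric_acid_cycle	Succinate dehydrogenase complex flavoprotein subunit A
SDHB	1.54	7E-24	24	citric_acid_cycle	Succinate dehydrogenase complex iron sulfur subunit B
SDHD	1.37	2E-07	15	citric_acid_cycle	Succinate dehydrogenase cytochrome b small subunit
MDH2	1.34	1E-21	57	citric_acid_cycle	Malate dehydrogenase 2, mitochondrial
G6PD	1.35	2E-14	21	pentose_phosphate	Glucose-6-phosphate dehydrogenase
PGLS	0.74	3E-08	21	pentose_phosphate	6-Phosphogluconolactonase
PGD	1.36	7E-25	89	pentose_phosphate	Phosphogluconate dehydrogenase
RPE	1.89	7E-33	13	pentose_phosphate	Ribulose 5-phosphate 3-epimerase
RPIA	1.98	3E-34	14	pentose_phosphate	Ribose 5-phosphate isomerase A
TKT	1.57	4E-61	57	pentose_phosphate	Transketolase
TALDO1	1.34	4E-17	47	pentose_phosphate	Transaldolase 1
ACLY	1.39	4E-32	119	citrate_shuttle	ATP citrate lyase
MPC1	2.06	3E-68	45	citrate_shuttle	Mitochondrial pyruvate carrier 1
PC	0.80	5E-08	15	citrate_shuttle	Pyruvate carboxylase
ACACA	1.98	3E-78	7	fatty_acid_synthesis	Acetyl-CoA carboxylase alpha
FASN	1.77	2E-91	156	fatty_acid_synthesis	Fatty acid synthase
ACSL1	2.00	2E-20	2	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 1
ACSL3	1.59	4E-50	30	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 3
ACSL4	1.92	5E-18	38	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 4
ACSL5	1.21	1E-07	28	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 5
ELOVL1	1.33	1E-09	18	fatty_acid_synthesis	ELOVL fatty acid elongase 1
ELOVL2	0.81	2E-07	34	fatty_acid_synthesis	ELOVL fatty acid elongase 2
ELOVL5	1.62	3E-30	30	fatty_acid_synthesis	ELOVL fatty acid elongase 5
HACD2	1.56	2E-29	15	fatty_acid_synthesis	Very-long-chain 3-hydroxyacyl-CoA dehydratase 2
HACD3	1.28	4E-13	21	fatty_acid_synthesis	3-Hydroxyacyl-CoA dehydratase 3
SLC25A20	0.50	9E-15	9	carnitine_shuttle	Mitochondrial carnitine/acylcarnitine carrier protein
CPT2	0.19	4E-88	3	carnitine_shuttle	Carnitine O-palmitoyltransferase 2, mitochondrial
ACADM	0.51	2E-36	4	fatty_acid_oxidation	Acyl-CoA dehydrogenase, medium chain
ECHS1	0.81	8E-10	138	fatty_acid_oxidation	Enoyl-CoA hydratase short chain 1
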