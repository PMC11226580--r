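gene	fold_change	p_value	baseline_rpkm	pathway	gene_name
GCK	3.16	1E-31	2	glycolysis	Glucokinase
HK1	2.49	4E-33	29	glycolysis	Hexokinase 1
HK2	3.72	6E-72	3	glycolysis	Hexokinase 2
GPI	3.25	3E-48	13	glycolysis	Glucose-6-phosphate isomerase
PFKM	1.89	6E-14	24	glycolysis	Phosphofructokinase, muscle
ALDOA	3.92	4E-62	45	glycolysis	Fructose-bisphosphate aldolase A
ALDOC	4.23	5E-75	11	glycolysis	Fructose-bisphosphate aldolase C
TPI1	2.82	1E-37	264	glycolysis	Triosephosphate isomerase 1
GAPDH	2.93	3E-36	642	glycolysis	Glyceraldehyde-3-phosphate dehydrogenase
PGAM2	2.82	3E-08	2	glycolysis	Phosphoglycerate mutase 2 (muscle)
ENO1	2.17	4E-25	157	glycolysis	Enolase 1
ENO2	2.38	5E-35	30	glycolysis	Enolase 2
ENO3	5.03	9E-10	531	glycolysis	Enolase 3
PKM	1.49	5E-07	91	glycolysis	Pyruvate kinase M1/2
CS	3.53	4E-65	31	citric_acid_cycle	Citrate synthase
ACO2	1.95	3E-17	33	citric_acid_cycle	Aconitase 2
IDH1	1.40	7E-07	53	citric_acid_cycle	Isocitrate dehydrogenase 1 (NADP+)
IDH2	1.93	9E-17	23	citric_acid_cycle	Isocitrate dehydrogenase 2 (NADP+)
IDH3B	1.93	4E-18	28	citric_acid_cycle	Isocitrate dehydrogenase 3 non-catalytic subunit beta
IDH3G	1.67	1E-08	13	citric_acid_cycle	Isocitrate dehydrogenase 3 non-catalytic subunit gamma
DLD	0.53	5E-14	19	citric_acid_cycle	Dihydrolipoamide dehydrogenase
SUCLG1	3.14	4E-47	18	citric_acid_cycle	Succinate-CoA ligase subunit alpha
SUCLG2	2.01	1E-08	2	citric_acid_cycle	Succinate-CoA ligase [GDP-forming] subunit beta
SDHA	1.73	7E-17	10	citric_acid_cycle	Succinate dehydrogenase complex flavoprotein subunit A
SDHB	1.80	2E-13	23	citric_acid_cycle	Succinate dehydrogenase complex iron sulfur subunit B
FH	2.81	5E-36	25	citric_acid_cycle	Fumarate hydratase
MDH2	2.71	4E-36	44	citric_acid_cycle	Malate dehydrogenase 2, mitochondrial
G6PD	1.75	9E-14	56	pentose_phosphate	Glucose-6-phosphate dehydrogenase
PGLS	2.13	1E-14	11	pentose_phosphate	6-Phosphogluconolactonase
PGD	3.16	3E-45	117	pentose_phosphate	Phosphogluconate dehydrogenase
TKT	8.63	4E-15	324	pentose_phosphate	Transketolase
SLC25A1	4.11	9E-78	16	citrate_shuttle	Solute carrier family 25 member 1
ACLY	1.47	2E-09	146	citrate_shuttle	ATP citrate lyase
ME1	7.78	2E-97	1	citrate_shuttle	Malic enzyme 1, cytosolic
ME2	1.79	3E-18	7	citrate_shuttle	Malic enzyme 2, mitochondrial
MPC2	2.89	4E-31	7	citrate_shuttle	Mitochondrial pyruvate carrier 2
ACACA	2.77	1E-53	11	fatty_acid_synthesis	Acetyl-CoA carboxylase alpha
ACSL1	0.44	3E-26	12	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 1
ACSL3	2.07	8E-11	18	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 3
ACSL4	1.92	7E-11	12	fatty_acid_synthesis	Long-chain-fatty-acid-CoA ligase 4
ELOVL1	2.10	2E-18	5	fatty_acid_synthesis	ELOVL fatty acid elongase 1
ELOVL5	2.69	4E-57	35	fatty_acid_synthesis	ELOVL fatty acid elongase 5
ELOVL6	1.69	8E-08	11	fatty_acid_synthesis	ELOVL fatty acid elongase 6
HACD2	0.46	2E-14	3	fatty_acid_synthesis	Very-long-chain 3-hydroxyacyl-CoA dehydratase 2
TECR	1.68	3E-11	14	fatty_acid_synthesis	Trans-2,3-enoyl-CoA reductase
SCD	7.78	8E-25	5160	fatty_acid_synthesis	Stearoyl-CoA desaturase
SCD5	1.73	1E-12	6	fatty_acid_synthesis	Stearoyl-CoA desaturase 5
ACADM	0.40	1E-18	13	fatty_acid_oxidation	Acyl-CoA dehydrogenase, medium chain
ACADVL	2.16	9E-23	20	fatty_acid_oxidation	Acyl-CoA dehydrogenase very long chain
ACAD9	0.50	1E-13	8	fatty_acid_oxidation	Acyl-CoA dehydrogenase family member 9
HADH	4.14	1E-67	6	fatty_acid_oxidation	Hydroxyacyl-CoA dehydrogenase
HADHA	1.69	9E-15	53	fatty_acid_oxidation	Trifunctional enzyme subunit alpha
HADHB	1.99	7E-23	20	fatty_acid_oxidation	Trifunctional enzyme subunit beta
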