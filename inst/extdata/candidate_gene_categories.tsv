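symbol	fold_change	p_value	chromosome	angiogenesis	cell_growth_and_proliferation	cell_death_and_survival	cell_morphology	cellular_movement	development	endocrine_system	estrogen_signaling	pituitary_tumors	sexual_dimorphism
BHLHE41	2.077	0.00365	12	0	0	0	0	1	1	0	1	0	0
CDK8	2.599	5.59e-5	13	0	1	0	0	0	0	0	1	0	0
CHL1	3.117	0.0296	3	0	1	0	1	1	1	0	0	1	0
CTAG2	2.332	0.0242	X	0	0	0	0	1	0	0	1	0	0
ENC1	2.023	0.0336	5	0	1	0	1	1	0	0	0	1	0
ERBIN	2.008	0.0191	5	0	1	0	1	0	1	0	1	0	1
ETS2	2.366	5.76e-4	21	0	0	1	0	0	1	0	1	1	0
EXT1	2.181	0.00196	8	0	1	0	0	1	1	0	1	0	0
EZR	-2.199	0.0187	6	0	1	0	1	1	1	0	0	1	0
FGF13	3.419	0.0067	X	0	1	1	1	1	1	0	1	0	0
FOXA1	2.35	0.0338	14	0	1	0	1	1	1	1	1	0	1
FOXQ1	5.758	0.0393	6	0	0	0	0	1	1	0	1	0	0
GADD45G	-2.656	0.0281	9	0	1	0	0	0	0	0	0	1	0
ISL1	2.163	0.0338	5	1	1	1	0	1	1	1	0	0	0
KDM5D	18.032	4.12e-10	Y	0	1	0	0	0	0	0	0	0	1
LTBP1	2.246	0.0367	2	1	1	1	0	0	1	0	1	1	1
MYH7	-4.706	0.00688	14	0	0	0	0	0	1	0	1	0	0
NMU	3.336	0.00721	4	0	0	0	0	1	0	0	1	0	0
OBSCN	2.596	0.0158	1	0	0	1	0	0	0	0	1	0	0
PITX1	2.459	0.00579	5	0	0	0	0	0	1	1	1	1	0
PPID	2.261	0.0369	4	0	0	0	0	1	0	0	0	0	1
PTGS1	2.554	0.0263	9	1	0	0	0	0	1	1	1	0	0
PTPRZ1	2.393	0.0496	7	1	1	0	1	1	1	0	1	0	0
ROBO1	2.033	0.0144	3	1	1	0	1	1	1	0	1	0	0
SLC12A4	3.348	0.00534	16	0	0	0	0	0	1	0	0	1	0
SLC2A11	2.342	0.0131	22	0	1	0	0	0	0	1	0	1	0
SLC6A8	2.577	0.00231	X	0	0	1	0	0	0	0	1	0	1
SNCB	2.022	0.013	5	0	0	0	1	0	1	0	1	0	0
SOSTDC1	6.814	0.0103	7	0	0	0	0	0	1	0	1	0	0
STAP2	2.122	0.00363	19	0	0	0	0	1	0	0	1	0	0
TSPAN8	3.232	0.0371	12	0	0	0	0	1	0	0	1	0	0
VEGFD	2.27	0.0363	X	1	1	0	1	1	1	0	0	1	0
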