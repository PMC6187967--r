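gene_name	group_id	species_id	gene_id	type	log2fc	adj_p
NFR1	NA	Ct	Ct_CtTrNR03429	ortholog	-0.37	0.151
NFR1	NA	Dg	Dg_DgTrNR03578	ortholog	2.75	0.000
NFR1	NA	Dg	Dg_DgTrNR03579	ortholog	-1.39	0.000
NFR1	NA	Dg	Dg_DgTrNR03580	ortholog	2.54	0.000
NFR1	NA	Mt	Mt_Medtr5g086130	ortholog	-2.10	0.000
NFR5	NA	Ct	Ct_CtTrNR01660	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR02016	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR02556	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR03429	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR03658	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR10088	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR13226	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR13284	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR14238	homolog	NA	NA
NFR5	NA	Ct	Ct_CtTrNR14293	homolog	NA	NA
NFR5	NA	Dg	Dg_DgTrNR09631	ortholog	-1.52	0.000
NFR5	NA	Mt	Mt_Medtr5g019040	ortholog	-2.43	0.000
SYMRK	MergedOrthoGroup005636	Ct	Ct_CtTrNR07134	ortholog	-0.19	0.413
SYMRK	MergedOrthoGroup005636	Dg	Dg_DgTrNR12393	ortholog	0.46	0.000
SYMRK	MergedOrthoGroup005636	Mt	Mt_Medtr5g030920	ortholog	0.60	0.002
SYMREM	MergedOrthoGroup006520	Ct	Ct_CtTrNR08408	ortholog	2.10	0.003
SYMREM	MergedOrthoGroup006520	Dg	Dg_DgTrNR05672	ortholog	5.65	0.000
SYMREM	MergedOrthoGroup006520	Mt	Mt_Medtr5g010590	ortholog	-0.22	0.775
SYMREM	MergedOrthoGroup006520	Mt	Mt_Medtr8g097320	ortholog	9.88	0.000
HMGR	NA	Ct	Ct_CtTrNR06569	homolog	NA	NA
HMGR	NA	Ct	Ct_CtTrNR06801	homolog	NA	NA
HMGR	NA	Ct	Ct_CtTrNR08716	homolog	NA	NA
HMGR	NA	Ct	Ct_CtTrNR12229	homolog	NA	NA
HMGR	NA	Dg	Dg_DgTrNR07804	homolog	NA	NA
HMGR	NA	Dg	Dg_DgTrNR14611	homolog	NA	NA
HMGR	NA	Dg	Dg_DgTrNR14612	homolog	NA	NA
HMGR	NA	Mt	Mt_Medtr5g087550	ortholog	-1.35	0.000
NUP85	MergedOrthoGroup003212	Ct	Ct_CtTrNR03893	ortholog	-0.87	0.020
NUP85	MergedOrthoGroup003212	Dg	Dg_DgTrNR02299	ortholog	0.12	0.132
NUP85	MergedOrthoGroup003212	Mt	Mt_Medtr1g006690	ortholog	-0.19	0.665
NUP133	MergedOrthoGroup009404	Ct	Ct_CtTrNR12969	ortholog	-0.20	0.263
NUP133	MergedOrthoGroup009404	Dg	Dg_DgTrNR15290	ortholog	0.58	0.000
NUP133	MergedOrthoGroup009404	Lj	Lj_Lj2g3v3337540	ortholog	NA	NA
NUP133	MergedOrthoGroup009404	Lj	Lj_Lj0g3v0050449	ortholog	NA	NA
NUP133	MergedOrthoGroup009404	Mt	Mt_Medtr5g097260	ortholog	-0.48	0.064
CASTOR	MergedOrthoGroup008762	Ct	Ct_CtTrNR11902	ortholog	-0.39	0.071
CASTOR	MergedOrthoGroup008762	Dg	Dg_DgTrNR14656	ortholog	0.37	0.001
CASTOR	MergedOrthoGroup008762	Mt	Mt_Medtr7g117580	ortholog	-0.23	0.431
POLLUX	MergedOrthoGroup009011	Ct	Ct_CtTrNR12292	ortholog	-0.43	0.090
POLLUX	MergedOrthoGroup009011	Dg	Dg_DgTrNR14917	ortholog	-0.83	0.000
POLLUX	MergedOrthoGroup009011	Mt	Mt_Medtr2g005870	ortholog	1.61	0.000
CCAMK	MergedOrthoGroup006145Sub001	Ct	Ct_CtTrNR07875	ortholog	-0.49	0.064
CCAMK	MergedOrthoGroup006145Sub001	Dg	Dg_DgTrNR14486	ortholog	0.02	0.857
CCAMK	MergedOrthoGroup006145Sub001	Mt	Mt_Medtr8g043970	ortholog	0.59	0.004
CYCLOPS	MergedOrthoGroup005459Sub002	Ct	Ct_CtTrNR09813	ortholog	0.25	0.294
CYCLOPS	MergedOrthoGroup005459Sub002	Dg	Dg_DgTrNR00459	ortholog	1.60	0.000
CYCLOPS	MergedOrthoGroup005459Sub002	Mt	Mt_Medtr5g026850	ortholog	3.18	0.000
NSP1	MergedOrthoGroup009317	Ct	Ct_CtTrNR12805	ortholog	-0.10	0.595
NSP1	MergedOrthoGroup009317	Dg	Dg_DgTrNR11911	ortholog	0.96	0.000
NSP1	MergedOrthoGroup009317	Mt	Mt_Medtr3g085310	ortholog	0.00	1.000
NSP1	MergedOrthoGroup009317	Mt	Mt_Medtr8g020840	ortholog	1.62	0.000
NSP2	MergedOrthoGroup000090	Ct	Ct_CtTrNR00101	ortholog	0.50	0.232
NSP2	MergedOrthoGroup000090	Dg	Dg_DgTrNR00363	ortholog	-1.38	0.000
NSP2	MergedOrthoGroup000090	Dg	Dg_DgTrNR01580	ortholog	0.99	0.001
NSP2	MergedOrthoGroup000090	Mt	Mt_Medtr3g072710	ortholog	-1.34	0.000
NSP2	MergedOrthoGroup000090	Mt	Mt_Medtr5g058860	ortholog	-2.59	0.000
ERN1	MergedOrthoGroup010414	Ct	Ct_CtTrNR15219	ortholog	-2.56	0.003
ERN1	MergedOrthoGroup010414	Dg	Dg_DgTrNR02845	ortholog	-0.66	0.006
ERN1	MergedOrthoGroup010414	Dg	Dg_DgTrNR10008	ortholog	4.95	0.000
ERN1	MergedOrthoGroup010414	Mt	Mt_Medtr6g029180	ortholog	-2.53	0.000
ERN1	MergedOrthoGroup010414	Mt	Mt_Medtr7g085810	ortholog	-0.39	0.373
NIN	MergedOrthoGroup008966	Ct	Ct_CtTrNR12221	ortholog	5.48	0.003
NIN	MergedOrthoGroup008966	Ct	Ct_CtTrNR12222	ortholog	6.47	0.004
NIN	MergedOrthoGroup008966	Dg	Dg_DgTrNR00885	ortholog	8.30	0.000
NIN	MergedOrthoGroup008966	Dg	Dg_DgTrNR00886	ortholog	7.56	0.000
NIN	MergedOrthoGroup008966	Mt	Mt_Medtr5g099060	ortholog	7.42	0.000
LHK1	MergedOrthoGroup007561	Ct	Ct_CtTrNR09972	ortholog	1.16	0.156
LHK1	MergedOrthoGroup007561	Dg	Dg_DgTrNR03717	ortholog	-0.92	0.000
LHK1	MergedOrthoGroup007561	Lj	Lj_Lj0g3v0108729	ortholog	NA	NA
LHK1	MergedOrthoGroup007561	Mt	Mt_Medtr2g067240	ortholog	0.00	1.000
LHK1	MergedOrthoGroup007561	Mt	Mt_Medtr5g044100	ortholog	0.00	1.000
LHK1	MergedOrthoGroup007561	Mt	Mt_Medtr8g106150	ortholog	-0.22	0.524
PIR	NA	Ct	Ct_CtTrNR13403	ortholog	0.13	0.688
PIR	NA	Dg	Dg_DgTrNR01709	ortholog	0.17	0.048
PIR	NA	Dg	Dg_DgTrNR07598	ortholog	-0.51	0.000
PIR	NA	Lj	Lj_Lj1g3v5020900	ortholog	NA	NA
RPG	MergedOrthoGroup006667Sub001	Ct	Ct_CtTrNR08628	ortholog	-0.78	0.022
RPG	MergedOrthoGroup006667Sub001	Ct	Ct_CtTrNR14741	ortholog	5.14	0.003
RPG	MergedOrthoGroup006667Sub001	Dg	Dg_DgTrNR05600	ortholog	8.90	0.000
RPG	MergedOrthoGroup006667Sub001	Dg	Dg_DgTrNR07056	ortholog	-0.25	0.102
RPG	MergedOrthoGroup006667Sub001	Mt	Mt_Medtr1g090807	ortholog	6.45	0.000
CERBERUS	MergedOrthoGroup002490Sub002	Ct	Ct_CtTrNR11435	ortholog	0.24	0.265
CERBERUS	MergedOrthoGroup002490Sub002	Dg	Dg_DgTrNR05473	ortholog	0.87	0.000
CERBERUS	MergedOrthoGroup002490Sub002	Mt	Mt_Medtr1g090320	ortholog	1.25	0.000
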