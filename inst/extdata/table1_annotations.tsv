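protein_id	name	tffd_start	tffd_end	tmd_index	tmd_start	tmd_end	tmd_score	topology	nls	localizations	ptm_kind	ptm_position	helix_motif	kr_tmd	kr_flank	n_alt_transcripts
AIL6	AIL6	389	440	1	301	321	0.702	I		mt;nuc				0	K3R1	2
AIL6											ph					
AIL6											ph					
AIL6											ph					
AIL6											ph					
ANAC028	ANAC028	6	143	1	609	630	0.57			nuc				K2	K5R1	
ANAC028											nt					
AT2G13960	AT2G13960	40	86	1	9	29	0.582	II		sec;nuc;PM			[GxxN]	0	K4	
AT2G29660	AT2G29660	126	149	1	9	29	0.477	I		sec;mt;nuc				R1	K6R4	
AT2G29660											ph					
AT3G04930	AT3G04930	137	235	1	372	395	0.486	II		nuc				0	K1	1
AT3G04930											ph					
AT3G04930											ph					
AT3G04930											ph					
AT3G04930											ph					
AT3G04930											ph					
AT5G25475	AT5G25475	78	155	1	52	75	0.606	I		mt			[PxxN]	K1	K1R5	2
AT5G63280	AT5G63280	105	128	1	223	246	0.836	II		sec;nuc				0	K4R1	
AT5G63280											nt					
AT5G63280											ng					
AT5G63280											ac					
AT5G63280											ro					
bHLH035	bHLH035	58	101	1	203	224	0.581	II		nuc				0	K2	3
bHLH035				2	190	213	0.36	II						K1	K2R1	
bHLH035				3	214	245	0.871	I					[PN]	R1		
bHLH035											ph					
bHLH115	bHLH115	136	182	1	190	211	0.363			nuc				K5	K1R2	
bHLH131	bHLH131	1351	1397	1	1242	1262	0.463			nuc;sec				0	K2	2
bHLH131				2	1277	1297	0.341							0		
bHLH131											ph					
bZIP7	bZIP7	197	254	1	38	59	0.662			nuc				K1	0	3
bZIP7											ph					
bZIP7											ph					
bZIP7											ph					
bZIP7											ng					
bZIP17	bZIP17	226	287	1	364	387	0.798	I		nuc			[GA]	K1	K7	
bZIP17											ph					
bZIP28	bZIP28	192	237	1	321	344	0.848	I		nuc;sec;ER				K1	K7R1	
bZIP49	bZIP49	172	219	1	286	309	0.755	I		nuc			[GA]	K1	K6R1	
bZIP60	bZIP60	141	183	1	217	240	0.693	II		nuc				0	K2R1	
CAMTA1	CAMTA1	81	188	1	192	211	0.38	I		nuc				R1	K1R3	
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											ph					
CAMTA1											na					
CAMTA1											nt					
CAMTA5	CAMTA5	30	146	1	579	600	0.683			nuc				0	K4	1
CAMTA5											ph					
CAMTA5											ph					
CAMTA5											ph					
CAMTA5											sm					
FRF3	FRF3	25	110	1	115	136	0.424			mt;cyt				R1	K2R1	1
GPL2	GPL2	61	155	1	328	348	0.786			nuc			[PxxP]	0	0	
GPL2											ph					
GPL2											ph					
GPL2											ph					
GPL2											ph					
HHO5	HHO5	218	272	1	64	85	0.567			nuc				R1	K3R1	3
HHO5											ph					
LD	LD	66	122	1	222	243	0.496			nuc				K1	K2R1	
LD											ph					
LD											ph					
LD											ub					
LHL2	LHL2	529	566	1	123	144	0.537			nuc				0	K1R4	2
LOL1	LOL1	70	171	1	24	47	0.488	II		sec;nuc				0	K3R1	
MAMYB	MAMYB	159	193	1	35	55	0.77	I		nuc				0	K1	
MAMYB				2	61	84	0.575	II					[PxxP]	K1		
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											ph					
MAMYB											na					
NFXL2	NFXL2	247	452	1	840	863	0.462	II		nuc				K1	K2R2	
NFXL2											ph					
NGAL2	NGAL2	29	142	1	198	221	0.469	II		nuc				0	K2	2
NLP3	NLP3	495	546	1	41	64	0.55	I		mt;nuc				0	0	
NOK	NOK	57	155	1	30	51	0.345			nuc				K1R1	K1R1	
NOK											nt					
NTL1	NTL1	10	135	1	497	520	0.792	I		nuc			[GA]	0	K7R1	
NTL2	NTL2	24	151	1	605	625	0.76	II		nuc				0	K5R1	
NTL3	NTL3	17	143	1	535	555	0.718	II		nuc			[GA]	K1	K2R2	
NTL4	NTL4	9	136	1	522	545	0.714	II		nuc;PM				K1	K1	
NTL5	NTL5	15	140	1	316	334	0.528	II		nuc				R1	K1R1	
NTL6	NTL6	13	141	1	442	462	0.523	II		nuc				R1	K3R1	
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL6											ph					
NTL7	NTL7	17	143	1	525	548	0.856	II		nuc;cyt			[GA]	R1	K3R2	
NTL7											ph					
NTL8	NTL8	14	140	1	312	332	0.759	II		nuc;PM				0	K4R2	
NTL9	NTL9	9	135	1	488	511	0.528	II		nuc;Golgi				K1R1	K2R5	
NTL10	NTL10	5	138	1	410	428	0.773	II		nuc				0	K2	
NTL10											ph					
NTL10											ph					
NTL10											ph					
NTL11	NTL11	9	136	1	541	564	0.571	II		nuc				K1R1	K1	
NTL11											ph					
NTL11											ph					
NTL13	NTL13	22	147	1	319	339	0.48	II		nuc				0	K2R1	
NTM1	NTM1	6	136	1	445	468	0.432	II		nuc				K2R2	K4R2	
NTM1											ph					
NTM1											ph					
NTM1											ph					
NTM1											ph					
OBP3	OBP3	118	177	1	42	62	0.595			mt;nuc				0	0	5
OBP3											ph					
OBP3											ph					
RLT2	RLT2	18	74	1	518	539	0.554			nuc				R1	K4	3
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ph					
RLT2											ac					
SCP	SCP	36	136	1	14	37	0.55	II		sec;nuc			[GA]	K1R1	K1R3	
SPL1	SPL1	105	182	1	835	858	0.641	II		nuc				R1	K2R2	
SPL1											ph					
SPL1											ph					
SPL1											ph					
SPL7	SPL7	137	213	1	762	782	0.627	II		nuc				0	K2R3	
SPL7											ph					
SPL12	SPL12	126	203	1	881	904	0.641	I		nuc				R1	K3R1	
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL12											ph					
SPL14	SPL14	119	196	1	995	1018	0.614	II		nuc				0	K1R3	
SPL14											ph					
SPL14											ph					
SPL14											ph					
SPL16	SPL16	82	158	1	978	1001	0.614	II		nuc				0	K2R3	
SRS8	SRS8	46	140	1	144	164	0.375	II		nuc				0	K1R1	3
SRS8											ph					
WIP4	WIP4	256	362	1	42	63	0.468			nuc;sec				0	K1R1	
ZFN2	ZFN2	45	334	1	444	465	0.72			nuc				K1	0	2
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											ph					
ZFN2											na					
ZFN2											nt					
ZFN2											my					
ZFN2											ub					
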