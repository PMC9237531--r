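name	notation	category	source	orientations	cleavage_offsets
RRIL	RRIL	protease_recognition	S1P exact	forward
S1P_degenerate	Rx[LIT][KL]	protease_recognition	S1P consensus	forward
rhomboid_NTL	LxLSIxGA	protease_recognition	Rho-1/Spitz-derived	forward	3;7
rhomboid_NTL_relaxed	[LF]xLSIxGA	protease_recognition	Rho-1/Spitz-derived	forward	3;7
rhomboid_consensus_xx	[ILMF]xx[GAS][AHS][IMLF]	protease_recognition	AarA/GlpG/Rho-1/PARL substrates	forward
rhomboid_consensus_x	[ILMF]x[GAS][AHS][IMLF]	protease_recognition	AarA/GlpG/Rho-1/PARL substrates	forward
pan_rhomboid	[^WP][IMYFWLV][^WPD][^WF][AGCS][^P][FIMVACLTW]	protease_recognition	minimal pan-rhomboid consensus	forward
NP	NP	helix_destabilizing	S1P substrates	both
NxxP	NxxP	helix_destabilizing	S1P substrates	both
PxxP	PxxP	helix_destabilizing	S1P substrates	both
GxxN	GxxN	helix_destabilizing	S1P substrates	both
PxxN	PxxN	helix_destabilizing	S1P substrates	both
PN	PN	helix_destabilizing	S1P substrates	both
GA	GA	helix_destabilizing	rhomboid substrates	both
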