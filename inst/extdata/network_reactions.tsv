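reaction_id	pathway	reversible	equation
G1	G	0	GLC + ATP -> G6P + ADP
G2	G	1	G6P <-> F6P
G3	G	0	F6P + ATP -> FBP + ADP
G4	G	1	FBP <-> DHAP + G3P
G5	G	1	DHAP <-> G3P
G6	G	1	G3P + NAD + PI <-> BPG + NADH
G7	G	1	BPG + ADP <-> 3PG + ATP
G8	G	1	3PG <-> 2PG
G9	G	1	2PG <-> PEP
G10	G	0	PEP + ADP -> PYR + ATP
PYP	PYP	0	PYR + NAD + HSCOA -> ACCOA + NADH + CO2
TCA1	TCA	0	OAA + ACCOA + H2O -> CIT + HSCOA
TCA2	TCA	1	CIT <-> ACON + H2O
TCA3	TCA	1	ACON + H2O <-> ICIT
TCA4	TCA	1	ICIT + NAD <-> AKG + CO2 + NADH
TCA5	TCA	0	AKG + NAD + HSCOA -> SUCCOA + CO2 + NADH
TCA6	TCA	1	SUCCOA + GDP + PI <-> SUC + GTP + HSCOA
TCA7	TCA	1	SUC + FAD <-> FUM + FADH2
TCA8	TCA	1	FADH2 + Q <-> FAD + QH2
TCA9	TCA	1	FUM + H2O <-> MAL
TCA10	TCA	1	MAL + NAD <-> OAA + NADH
PPP1	PPP	0	G6P + NADP -> 6PGL + NADPH
PPP2	PPP	0	6PGL + H2O -> 6PG
PPP3	PPP	0	6PG + NADP -> RU5P + CO2 + NADPH
PPP4	PPP	1	RU5P <-> R5P
PPP5	PPP	1	RU5P <-> X5P
PPP6	PPP	1	X5P + R5P <-> S7P + G3P
PPP7	PPP	1	S7P + G3P <-> E4P + F6P
PPP8	PPP	1	X5P + E4P <-> F6P + G3P
ETC1	ETC	0	NADH + Q -> NAD + QH2 + 4 HX
ETC2	ETC	0	QH2 + 0.5 O2 -> Q + H2O + 6 HX
ETC3	ETC	0	ADP + PI + 3 HX -> ATP + H2O
AP1	AP	0	PYR + CO2 + ATP -> OAA + ADP + PI
AP2	AP	1	ASP + AKG <-> OAA + GLU
AP3	AP	1	PYR + GLU <-> ALA + AKG
AP4	AP	0	GLN + H2O -> GLU + NH4
LDH	LDH	0	PYR + NADH -> LAC + NAD
GDH	GDH	1	GLU + NAD + H2O <-> AKG + NADH + NH4
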