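alias	canonical
NB-ARC	NBARC
NB_ARC	NBARC
NBS	NBARC
NB	NBARC
NBD	NBARC
TIR_DOM	TIR
TIR_2	TIR
COILED-COIL	CC
COILED_COIL	CC
COIL	CC
CC_DOM	CC
LRR_1	LRR
LRR_4	LRR
LRR_8	LRR
LRR_RI	LRR
LRRNT	LRR
PKINASE	KINASE
PKINASE_TYR	KINASE
PROTEIN_KINASE	KINASE
STK	KINASE
KIN	KINASE
LYSM_DOM	LYSM
LYSIN	LYSM
TRANSMEMBRANE	TM
TMHMM	TM
TM_REGION	TM
TM_HELIX	TM
RPW8_DOM	RPW8
ECTODOMAIN	OTHER_ECTO
ECTO	OTHER_ECTO
MALECTIN	OTHER_ECTO
GNK2	OTHER_ECTO
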