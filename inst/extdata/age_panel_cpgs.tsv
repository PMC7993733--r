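marker	label	genomic_pos	amplicon_offset	array_id	coord_source
ELOVL2	C1	11044660	160		synthetic
ELOVL2	C2	11044655	155	cg24724428	paper
ELOVL2	C3	11044650	150		synthetic
ELOVL2	C4	11044646	146		synthetic
ELOVL2	C5	11044642	142		synthetic
ELOVL2	C6	11044638	138		synthetic
ELOVL2	C7	11044634	134		paper
ELOVL2	C8	11044631	131		synthetic
ELOVL2	C9	11044628	128		paper
MIR29B2CHG	C1	207823681	76		paper
MIR29B2CHG	C2	207823676	71		synthetic
MIR29B2CHG	C3	207823672	67		paper
KLF14	C1	130734355	48	cg14361627	paper
KLF14	C2	130734365	58		synthetic
KLF14	C3	130734372	65		paper
KLF14	C4	130734375	68		paper
TRIM59	C1	160450174	34		synthetic
TRIM59	C2	160450178	38		synthetic
TRIM59	C3	160450182	42		synthetic
TRIM59	C4	160450186	46		synthetic
TRIM59	C5	160450190	50		synthetic
TRIM59	C6	160450194	54		synthetic
TRIM59	C7	160450198	58		synthetic
TRIM59	C8	160450202	62		paper
FHL2	C1	105399282	32	cg06639320	paper
FHL2	C2	105399288	38		synthetic
FHL2	C3	105399294	44		synthetic
FHL2	C4	105399300	50		synthetic
FHL2	C5	105399306	56		synthetic
FHL2	C6	105399312	62		synthetic
FHL2	C7	105399318	68		synthetic
FHL2	C8	105399324	74		synthetic
FHL2	C9	105399330	80		synthetic
FHL2	C10	105399336	86		synthetic
PDE4C	C1	18233073	120		synthetic
PDE4C	C2	18233083	130		synthetic
PDE4C	C3	18233093	140		synthetic
PDE4C	C4	18233105	152		paper
PDE4C	C5	18233127	174		paper
PDE4C	C6	18233131	178	cg01481989	paper
PDE4C	C7	18233138	185		synthetic
EDARADD	C1	236394383	118	cg09809672	paper
EDARADD	C2	236394371	130		synthetic
ASPA	C1	3476273	66	cg02228185	paper
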