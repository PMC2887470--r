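aa3	bead_index	member_atoms
ALA	1	CA
ALA	2	CB
ARG	1	CA
ARG	2	CB,CG,CD
ARG	3	NE,CZ,NH1,NH2
ASN	1	CA
ASN	2	CB,CG,OD1,ND2
ASP	1	CA
ASP	2	CB,CG,OD1,OD2
CYS	1	CA
CYS	2	CB,SG
GLN	1	CA
GLN	2	CB,CG
GLN	3	CD,OE1,NE2
GLU	1	CA
GLU	2	CB,CG
GLU	3	CD,OE1,OE2
GLY	1	CA
HIS	1	CA
HIS	2	CB
HIS	3	CG,ND1,CD2,CE1,NE2
ILE	1	CA
ILE	2	CB,CG1,CG2,CD1
LEU	1	CA
LEU	2	CB,CG,CD1,CD2
LYS	1	CA
LYS	2	CB,CG,CD
LYS	3	CE,NZ
MET	1	CA
MET	2	CB,CG
MET	3	SD,CE
PHE	1	CA
PHE	2	CB,CG
PHE	3	CD1,CD2,CE1,CE2,CZ
PRO	1	CA
PRO	2	CB,CG
PRO	3	CD
SER	1	CA
SER	2	CB,OG
THR	1	CA
THR	2	CB,OG1,CG2
TRP	1	CA
TRP	2	CB,CG
TRP	3	CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2
TYR	1	CA
TYR	2	CB,CG
TYR	3	CD1,CD2,CE1,CE2,CZ,OH
VAL	1	CA
VAL	2	CB,CG1,CG2
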