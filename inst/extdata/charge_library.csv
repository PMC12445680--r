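residue,atom,charge,radius
ALA,N,0,1.55
ALA,CA,0,1.7
ALA,C,0,1.7
ALA,O,0,1.52
ALA,CB,0,1.7
ARG,N,0,1.55
ARG,CA,0,1.7
ARG,C,0,1.7
ARG,O,0,1.52
ARG,CB,0,1.7
ARG,CG,0,1.7
ARG,CD,0,1.7
ARG,NE,0,1.55
ARG,CZ,0,1.7
ARG,NH1,0.5,1.55
ARG,NH2,0.5,1.55
ASN,N,0,1.55
ASN,CA,0,1.7
ASN,C,0,1.7
ASN,O,0,1.52
ASN,CB,0,1.7
ASN,CG,0,1.7
ASN,OD1,0,1.52
ASN,ND2,0,1.55
ASP,N,0,1.55
ASP,CA,0,1.7
ASP,C,0,1.7
ASP,O,0,1.52
ASP,CB,0,1.7
ASP,CG,0,1.7
ASP,OD1,-0.5,1.52
ASP,OD2,-0.5,1.52
CYS,N,0,1.55
CYS,CA,0,1.7
CYS,C,0,1.7
CYS,O,0,1.52
CYS,CB,0,1.7
CYS,SG,0,1.8
GLN,N,0,1.55
GLN,CA,0,1.7
GLN,C,0,1.7
GLN,O,0,1.52
GLN,CB,0,1.7
GLN,CG,0,1.7
GLN,CD,0,1.7
GLN,OE1,0,1.52
GLN,NE2,0,1.55
GLU,N,0,1.55
GLU,CA,0,1.7
GLU,C,0,1.7
GLU,O,0,1.52
GLU,CB,0,1.7
GLU,CG,0,1.7
GLU,CD,0,1.7
GLU,OE1,-0.5,1.52
GLU,OE2,-0.5,1.52
GLY,N,0,1.55
GLY,CA,0,1.7
GLY,C,0,1.7
GLY,O,0,1.52
HIS,N,0,1.55
HIS,CA,0,1.7
HIS,C,0,1.7
HIS,O,0,1.52
HIS,CB,0,1.7
HIS,CG,0,1.7
HIS,ND1,0,1.55
HIS,CD2,0,1.7
HIS,CE1,0,1.7
HIS,NE2,0,1.55
ILE,N,0,1.55
ILE,CA,0,1.7
ILE,C,0,1.7
ILE,O,0,1.52
ILE,CB,0,1.7
ILE,CG1,0,1.7
ILE,CG2,0,1.7
ILE,CD1,0,1.7
LEU,N,0,1.55
LEU,CA,0,1.7
LEU,C,0,1.7
LEU,O,0,1.52
LEU,CB,0,1.7
LEU,CG,0,1.7
LEU,CD1,0,1.7
LEU,CD2,0,1.7
LYS,N,0,1.55
LYS,CA,0,1.7
LYS,C,0,1.7
LYS,O,0,1.52
LYS,CB,0,1.7
LYS,CG,0,1.7
LYS,CD,0,1.7
LYS,CE,0,1.7
LYS,NZ,1,1.55
MET,N,0,1.55
MET,CA,0,1.7
MET,C,0,1.7
MET,O,0,1.52
MET,CB,0,1.7
MET,CG,0,1.7
MET,SD,0,1.8
MET,CE,0,1.7
PHE,N,0,1.55
PHE,CA,0,1.7
PHE,C,0,1.7
PHE,O,0,1.52
PHE,CB,0,1.7
PHE,CG,0,1.7
PHE,CD1,0,1.7
PHE,CD2,0,1.7
PHE,CE1,0,1.7
PHE,CE2,0,1.7
PHE,CZ,0,1.7
PRO,N,0,1.55
PRO,CA,0,1.7
PRO,C,0,1.7
PRO,O,0,1.52
PRO,CB,0,1.7
PRO,CG,0,1.7
PRO,CD,0,1.7
SER,N,0,1.55
SER,CA,0,1.7
SER,C,0,1.7
SER,O,0,1.52
SER,CB,0,1.7
SER,OG,0,1.52
THR,N,0,1.55
THR,CA,0,1.7
THR,C,0,1.7
THR,O,0,1.52
THR,CB,0,1.7
THR,OG1,0,1.52
THR,CG2,0,1.7
TRP,N,0,1.55
TRP,CA,0,1.7
TRP,C,0,1.7
TRP,O,0,1.52
TRP,CB,0,1.7
TRP,CG,0,1.7
TRP,CD1,0,1.7
TRP,CD2,0,1.7
TRP,NE1,0,1.55
TRP,CE2,0,1.7
TRP,CE3,0,1.7
TRP,CZ2,0,1.7
TRP,CZ3,0,1.7
TRP,CH2,0,1.7
TYR,N,0,1.55
TYR,CA,0,1.7
TYR,C,0,1.7
TYR,O,0,1.52
TYR,CB,0,1.7
TYR,CG,0,1.7
TYR,CD1,0,1.7
TYR,CD2,0,1.7
TYR,CE1,0,1.7
TYR,CE2,0,1.7
TYR,CZ,0,1.7
TYR,OH,0,1.52
VAL,N,0,1.55
VAL,CA,0,1.7
VAL,C,0,1.7
VAL,O,0,1.52
VAL,CB,0,1.7
VAL,CG1,0,1.7
VAL,CG2,0,1.7
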