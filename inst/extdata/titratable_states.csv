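residue,kind,state,atom,charge
ASP,acid,deprot,OD1,-0.5
ASP,acid,deprot,OD2,-0.5
ASP,acid,prot,OD1,0
ASP,acid,prot,OD2,0
GLU,acid,deprot,OE1,-0.5
GLU,acid,deprot,OE2,-0.5
GLU,acid,prot,OE1,0
GLU,acid,prot,OE2,0
CYS,acid,deprot,SG,-1
CYS,acid,prot,SG,0
TYR,acid,deprot,OH,-1
TYR,acid,prot,OH,0
LYS,base,deprot,NZ,0
LYS,base,prot,NZ,1
ARG,base,deprot,NH1,0
ARG,base,deprot,NH2,0
ARG,base,prot,NH1,0.5
ARG,base,prot,NH2,0.5
HIS,his_tautomer,HIE,ND1,-0.2
HIS,his_tautomer,HIE,NE2,0.2
HIS,his_tautomer,HIP,ND1,0.5
HIS,his_tautomer,HIP,NE2,0.5
HIS,his_tautomer,HID,ND1,0.2
HIS,his_tautomer,HID,NE2,-0.2
TRP,redox,red,CG,0
TRP,redox,red,CD1,0
TRP,redox,red,CD2,0
TRP,redox,red,NE1,0
TRP,redox,red,CE2,0
TRP,redox,red,CE3,0
TRP,redox,red,CZ2,0
TRP,redox,red,CZ3,0
TRP,redox,red,CH2,0
TRP,redox,ox,CG,0.1
TRP,redox,ox,CD1,0.12
TRP,redox,ox,CD2,0.08
TRP,redox,ox,NE1,0.3
TRP,redox,ox,CE2,0.1
TRP,redox,ox,CE3,0.08
TRP,redox,ox,CZ2,0.08
TRP,redox,ox,CZ3,0.07
TRP,redox,ox,CH2,0.07
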