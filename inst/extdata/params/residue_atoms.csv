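res,atom,element,parents,donor,acceptor,charged_group,charge,lj_type,solv_type
*,N,N,CA,1,0,0,-0.30,N,NH1
*,CA,C,N;C;CB,0,0,0,0.30,CT,CH1E
*,C,C,CA;O,0,0,0,0.50,C,C
*,O,O,C,0,1,0,-0.50,O,O
*,OXT,O,C,0,1,0,0.00,O2,OC
ALA,CB,C,CA,0,0,0,0.00,CT,CH3E
ARG,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
ARG,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
ARG,CD,C,CG;NE,0,0,0,0.00,CT,CH2E
ARG,NE,N,CD;CZ,1,0,1,0.00,N3,NC2
ARG,CZ,C,NE;NH1;NH2,0,0,0,0.40,C,C
ARG,NH1,N,CZ,2,0,1,0.30,N3,NC2
ARG,NH2,N,CZ,2,0,1,0.30,N3,NC2
ASN,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
ASN,CG,C,CB;OD1;ND2,0,0,0,0.55,C,C
ASN,OD1,O,CG,0,1,0,-0.55,O,O
ASN,ND2,N,CG,2,0,0,0.00,N,NH1
ASP,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
ASP,CG,C,CB;OD1;OD2,0,0,0,-0.10,C,C
ASP,OD1,O,CG,0,1,1,-0.45,O2,OC
ASP,OD2,O,CG,0,1,1,-0.45,O2,OC
CYS,CB,C,CA;SG,0,0,0,0.10,CT,CH2E
CYS,SG,S,CB,0,0,0,-0.10,S,S
GLN,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
GLN,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
GLN,CD,C,CG;OE1;NE2,0,0,0,0.55,C,C
GLN,OE1,O,CD,0,1,0,-0.55,O,O
GLN,NE2,N,CD,2,0,0,0.00,N,NH1
GLU,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
GLU,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
GLU,CD,C,CG;OE1;OE2,0,0,0,-0.10,C,C
GLU,OE1,O,CD,0,1,1,-0.45,O2,OC
GLU,OE2,O,CD,0,1,1,-0.45,O2,OC
HIS,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
HIS,CG,C,CB;ND1;CD2,0,0,0,0.10,CA,CR
HIS,ND1,N,CG;CE1,1,0,0,-0.15,N,NH1
HIS,CD2,C,CG;NE2,0,0,0,0.10,CA,CR
HIS,CE1,C,ND1;NE2,0,0,0,0.10,CA,CR
HIS,NE2,N,CD2;CE1,0,1,0,-0.15,N,NH1
ILE,CB,C,CA;CG1;CG2,0,0,0,0.00,CT,CH1E
ILE,CG1,C,CB;CD1,0,0,0,0.00,CT,CH2E
ILE,CG2,C,CB,0,0,0,0.00,CT,CH3E
ILE,CD1,C,CG1,0,0,0,0.00,CT,CH3E
LEU,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
LEU,CG,C,CB;CD1;CD2,0,0,0,0.00,CT,CH1E
LEU,CD1,C,CG,0,0,0,0.00,CT,CH3E
LEU,CD2,C,CG,0,0,0,0.00,CT,CH3E
LYS,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
LYS,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
LYS,CD,C,CG;CE,0,0,0,0.00,CT,CH2E
LYS,CE,C,CD;NZ,0,0,0,0.40,CT,CH2E
LYS,NZ,N,CE,3,0,1,0.60,N3,NH3
MET,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
MET,CG,C,CB;SD,0,0,0,0.10,CT,CH2E
MET,SD,S,CG;CE,0,0,0,-0.20,S,S
MET,CE,C,SD,0,0,0,0.10,CT,CH3E
PHE,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
PHE,CG,C,CB;CD1;CD2,0,0,0,0.00,CA,CR
PHE,CD1,C,CG;CE1,0,0,0,0.00,CA,CR
PHE,CD2,C,CG;CE2,0,0,0,0.00,CA,CR
PHE,CE1,C,CD1;CZ,0,0,0,0.00,CA,CR
PHE,CE2,C,CD2;CZ,0,0,0,0.00,CA,CR
PHE,CZ,C,CE1;CE2,0,0,0,0.00,CA,CR
PRO,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
PRO,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
PRO,CD,C,CG;N,0,0,0,0.00,CT,CH2E
SER,CB,C,CA;OG,0,0,0,0.25,CT,CH2E
SER,OG,O,CB,1,1,0,-0.25,OH,OH1
THR,CB,C,CA;OG1;CG2,0,0,0,0.25,CT,CH1E
THR,OG1,O,CB,1,1,0,-0.25,OH,OH1
THR,CG2,C,CB,0,0,0,0.00,CT,CH3E
TRP,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
TRP,CG,C,CB;CD1;CD2,0,0,0,0.00,CA,CR
TRP,CD1,C,CG;NE1,0,0,0,0.10,CA,CR
TRP,CD2,C,CG;CE2;CE3,0,0,0,0.00,CA,CR
TRP,NE1,N,CD1;CE2,1,0,0,-0.20,N,NH1
TRP,CE2,C,NE1;CD2;CZ2,0,0,0,0.10,CA,CR
TRP,CE3,C,CD2;CZ3,0,0,0,0.00,CA,CR
TRP,CZ2,C,CE2;CH2,0,0,0,0.00,CA,CR
TRP,CZ3,C,CE3;CH2,0,0,0,0.00,CA,CR
TRP,CH2,C,CZ2;CZ3,0,0,0,0.00,CA,CR
TYR,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
TYR,CG,C,CB;CD1;CD2,0,0,0,0.00,CA,CR
TYR,CD1,C,CG;CE1,0,0,0,0.00,CA,CR
TYR,CD2,C,CG;CE2,0,0,0,0.00,CA,CR
TYR,CE1,C,CD1;CZ,0,0,0,0.00,CA,CR
TYR,CE2,C,CD2;CZ,0,0,0,0.00,CA,CR
TYR,CZ,C,CE1;CE2;OH,0,0,0,0.25,CA,CR
TYR,OH,O,CZ,1,1,0,-0.25,OH,OH1
VAL,CB,C,CA;CG1;CG2,0,0,0,0.00,CT,CH1E
VAL,CG1,C,CB,0,0,0,0.00,CT,CH3E
VAL,CG2,C,CB,0,0,0,0.00,CT,CH3E
CBA,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
CBA,CG,C,CB;CD1;CD2,0,0,0,0.00,CT,CH1E
CBA,CD1,C,CG;CE,0,0,0,0.00,CT,CH2E
CBA,CD2,C,CG;CE,0,0,0,0.00,CT,CH2E
CBA,CE,C,CD1;CD2,0,0,0,0.00,CT,CH2E
S5,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
S5,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
S5,CD,C,CG;CE,0,0,0,0.00,CT,CH2E
S5,CE,C,CD,0,0,0,0.00,CT,CH2E
R8,CB,C,CA;CG,0,0,0,0.00,CT,CH2E
R8,CG,C,CB;CD,0,0,0,0.00,CT,CH2E
R8,CD,C,CG;CE,0,0,0,0.00,CT,CH2E
R8,CE,C,CD,0,0,0,0.00,CT,CH2E
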