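name,charge,radius,epsilon,mass,transfer_energy
ALA,0.0,2.5,0.20,71.08,-0.5
ARG,1.0,3.3,0.25,156.19,2.0
ASN,0.0,2.8,0.22,114.10,0.9
ASP,-1.0,2.8,0.22,115.09,1.3
CYS,0.0,2.7,0.22,103.14,-1.0
GLN,0.0,3.0,0.23,128.13,0.8
GLU,-1.0,3.0,0.23,129.12,1.2
GLY,0.0,2.3,0.18,57.05,0.0
HIS,0.0,3.0,0.24,137.14,0.5
ILE,0.0,3.1,0.24,113.16,-2.5
LEU,0.0,3.1,0.24,113.16,-2.3
LYS,1.0,3.2,0.24,128.17,1.8
MET,0.0,3.1,0.24,131.19,-1.7
PHE,0.0,3.2,0.26,147.18,-2.4
PRO,0.0,2.8,0.22,97.12,0.1
SER,0.0,2.6,0.20,87.08,0.4
THR,0.0,2.8,0.21,101.10,0.3
TRP,0.0,3.4,0.28,186.21,-2.1
TYR,0.0,3.2,0.26,163.18,-0.7
VAL,0.0,2.9,0.22,99.13,-1.7
DA,-1.0,4.0,0.30,313.21,2.5
DC,-1.0,4.0,0.30,289.18,2.5
DG,-1.0,4.0,0.30,329.21,2.5
DT,-1.0,4.0,0.30,304.20,2.5
A,-1.0,4.0,0.30,329.21,2.5
C,-1.0,4.0,0.30,305.18,2.5
G,-1.0,4.0,0.30,345.21,2.5
U,-1.0,4.0,0.30,306.17,2.5
T,-1.0,4.0,0.30,320.19,2.5
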