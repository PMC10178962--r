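HO-1/HMOX1
Endoglin/CD105
CXCL8/IL8
CTSS
GRN
LGALS3
BIRC5
GM-CSF
ICAM-1
DKK-1
SPARC/BM-40
CAPG
P53
FGF2
ENO2
MMP2
EGFR
VIM
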