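# Canonical stromal marker genes (HGNC symbols): fibroblast, extracellular
# matrix, and mesenchymal markers commonly used in expression-based stromal
# signatures for bulk tumor data.
COL1A1
COL1A2
COL3A1
COL5A1
COL5A2
COL6A1
COL6A2
COL6A3
COL14A1
FN1
FBN1
DCN
LUM
POSTN
FAP
PDGFRA
PDGFRB
ACTA2
TAGLN
THY1
SPARC
MMP2
TIMP2
FBLN1
FBLN2
MGP
OGN
AEBP1
CDH11
THBS2
VCAN
ELN
SFRP2
SFRP4
ISLR
MXRA8
PCOLCE
GREM1
CTSK
COL10A1
COL11A1
MFAP5
ASPN
PRRX1
ZEB1
CD248
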