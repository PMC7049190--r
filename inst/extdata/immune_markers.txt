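# Canonical leukocyte marker genes (HGNC symbols): pan-leukocyte, T/B/NK
# lymphocyte, and myeloid lineage markers commonly used in expression-based
# immune signatures for bulk tumor data.
PTPRC
CD2
CD3D
CD3E
CD3G
CD8A
CD27
CD28
IL7R
LCK
ZAP70
CD52
CXCR4
CCR7
SELL
GZMA
GZMB
GZMK
PRF1
NKG7
KLRB1
KLRD1
CCL5
CD79A
CD79B
CD19
MS4A1
IGHM
TNFRSF17
FCGR3A
CD14
CD68
CSF1R
TYROBP
FCER1G
LYZ
AIF1
ITGAM
IL2RG
CD37
CD53
LAPTM5
PTPN22
SLAMF1
CD48
CD5
TRAC
TRBC1
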