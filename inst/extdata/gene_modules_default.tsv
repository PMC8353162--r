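module	gene
neural	NCAM1
neural	TUBB2B
neural	MAP1B
neural	CRABP1
mesoderm	TBX6
mesoderm	MEOX1
mesoderm	MSGN1
mesoderm	PAX1
mesoderm	TWIST1
blood	HBA1
blood	HBG1
blood	GATA1
blood	KLF1
skin	KRT5
skin	KRT8
skin	KRT18
skin	TP63
progenitor	SOX2
neuron	ELAVL3
neuron	STMN2
neuron	MAP2
gliogenic	FABP7
gliogenic	SOX9
gliogenic	SOX10
gliogenic	PDGFRA
gliogenic	CSPG4
gliogenic	FGFR3
gliogenic	FGFBP3
gliogenic	DBI
gliogenic	SLC1A3
gliogenic	HOPX
gliogenic	ALDH1L1
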