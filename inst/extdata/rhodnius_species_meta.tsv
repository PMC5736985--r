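species_id	taxon_group	hematophagous
RPRO	Hemiptera	1
ISCA	NonInsect	1
DPUL	NonInsect	0
TCAS	MixedInsect	0
AAEG	Diptera	1
AGAM	Diptera	1
CQUI	Diptera	1
DMEL	Diptera	0
DPSE	Diptera	0
GMOR	Diptera	1
APIS	Hemiptera	0
AMEL	Hymenoptera	0
AECH	Hymenoptera	0
CFLO	Hymenoptera	0
HSAL	Hymenoptera	0
SINV	Hymenoptera	0
NVIT	Hymenoptera	0
DPLE	MixedInsect	0
PHUM	MixedInsect	1
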