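family	RPRO	ISCA	DPUL	TCAS	AAEG	AGAM	CQUI	DMEL	DPSE	GMOR	APIS	AMEL	AECH	CFLO	HSAL	SINV	NVIT	DPLE	PHUM
M74	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
N6	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
S24	3	0	0	0	0	0	0	0	0	0	3	1	0	0	0	0	0	0	0
S29	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
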