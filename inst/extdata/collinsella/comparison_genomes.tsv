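organism	strain	accession	size_mb	gc_percent	genes	code
Collinsella massiliensis	GD3	CAPI00000000	2.32	65.8	2054	CM
Collinsella intestinalis	DSM 13280	ABXH00000000	1.8	62.5	1846	CI
Collinsella aerofaciens	ATCC 25986	AAVN00000000	2.44	60.6	2437	CA
Collinsella stercoris	DSM 13279	ABXJ00000000	2.4	63.2	2585	CS
Collinsella tanakaei	YIT 12063	ADLS00000000	2.48	60.2	2276	CT
Eggerthella lenta	DSM 2243	CP001726	3.63	64.2	3184	EL
Coriobacterium glomerans	PW2	CP002628	2.12	60.4	1858	CG
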