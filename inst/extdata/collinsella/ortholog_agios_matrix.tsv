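genome	CM	CA	CI	CS	CT	EL	CG
CM	2003	74.61	75.95	76.51	74.37	71.24	73.73
CA	947	2367	74.91	75.05	74.19	68.55	71.63
CI	867	945	1784	81.80	75.67	69.28	72.42
CS	953	999	1110	2529	75.70	69.88	72.53
CT	1029	1082	1108	1151	2212	68.46	71.50
EL	751	764	740	777	856	3070	68.52
CG	841	841	818	861	898	639	1768
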