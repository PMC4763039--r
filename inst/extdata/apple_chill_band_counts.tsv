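sample	type_I	type_II	type_III	type_IV
DBH	444	33	50	83
DBL	458	32	50	62
STH	446	37	59	70
STL	438	50	54	43
GTH	466	30	62	59
GTL	434	35	76	34
FSH	454	32	63	26
FSL	410	49	52	29
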