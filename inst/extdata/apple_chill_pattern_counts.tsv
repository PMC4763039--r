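class	DBL-vs-DBH	STL-vs-STH	GTL-vs-GTH	FSL-vs-FSH
A	432	420	420	402
B	23	30	28	27
C	44	50	56	49
D	62	43	34	29
E	10	2	0	0
F	8	6	8	2
G	8	10	6	6
H	0	2	0	1
I	7	11	5	4
J	6	3	8	2
K	2	7	2	17
L	0	1	12	1
M	0	0	0	0
N	0	0	0	0
O	0	0	0	0
P	0	0	0	0
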