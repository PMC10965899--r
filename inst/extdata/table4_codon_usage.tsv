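codon	aa_printed	count	rscu_printed
UUU	F	345	1.78
UUC	F	42	0.22
UUA	L	491	5.4
UUG	L	2	0.02
CUU	L	40	0.44
CUC	L	0	0
CUA	L	12	0.13
CUG	L	1	0.01
AUU	I	384	1.9
AUC	I	20	0.1
AUA	I	249	1.87
AUG	M	18	0.13
GUU	V	80	1.93
GUC	V	3	0.07
GUA	V	80	1.93
GUG	V	3	0.07
UCU	S	108	2.73
UCC	S	6	0.15
UCA	S	84	2.13
UCG	S	4	0.1
CCU	P	60	1.98
CCC	P	12	0.4
CCA	P	49	1.62
CCG	P	0	0
ACU	T	86	2.15
ACC	T	13	0.33
ACA	T	59	1.48
ACG	T	2	0.05
GCU	A	67	2.14
GCC	A	7	0.22
GCA	A	50	1.6
GCG	A	1	0.03
UAU	Y	196	1.88
UAC	Y	12	0.12
UAA	*	12	1.85
UAG	*	1	0.15
CAU	H	60	1.85
CAC	H	5	0.15
CAA	Q	59	1.93
CAG	Q	2	0.07
AAU	N	227	1.88
AAC	N	14	0.12
AAA	K	98	1.68
AAG	K	19	0.32
GAU	D	68	1.92
GAC	D	3	0.08
GAA	E	67	1.84
GAG	E	6	0.16
UGU	C	33	1.78
UGC	C	4	0.22
UGA	*	91	1.92
UGG	W	4	0.08
CGU	R	13	1.02
CGC	R	1	0.08
CGA	R	36	2.82
CGG	R	1	0.08
AGU	S	32	0.81
AGC	S	1	0.03
AGA	R	81	2.05
AGG	R	0	0
GGU	G	48	0.96
GGC	G	1	0.02
GGA	G	130	2.6
GGG	G	21	0.42
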