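class	size_bp	pct_A	pct_T	pct_G	pct_C	pct_AT	at_skew_printed	gc_skew_printed
PCG	11172	34	45.2	10.9	9.9	79.2	-0.141	0.048
tRNA	1467	41.1	39.8	10.8	8.3	80.9	0.016	0.131
rRNA	2108	42.9	41.8	10.2	5.1	84.7	0.012	0.333
control	1363	46.2	49.4	1.3	3.1	95.6	-0.033	-0.409
genome	16407	41.4	40.5	7.5	10.6	81.9	0.011	-0.17
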