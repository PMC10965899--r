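name	category	strand	start	stop	anticodon	size_printed	gap_printed	start_codon	stop_codon
trnS1	tRNA	+	42	102	gct	61	4	NA	NA
trnE	tRNA	+	107	172	ttc	66	5	NA	NA
trnF	tRNA	-	178	245	gaa	68	27	NA	NA
NADH5	PCG	-	273	1985	NA	1713	15	ATT	TAA
trnH	tRNA	-	2001	2068	gtg	68	28	NA	NA
NADH4	PCG	-	2097	3437	NA	1341	7	ATG	TAA
NADH4L	PCG	-	3445	3723	NA	279	21	ATG	TAA
trnT	tRNA	+	3745	3809	tgt	65	0	NA	NA
trnP	tRNA	-	3810	3874	tgg	65	26	NA	NA
NADH6	PCG	+	3901	4404	NA	504	3	ATT	TAA
CYTB	PCG	+	4408	5562	NA	1155	2	ATG	TAA
trnS2	tRNA	+	5565	5629	tga	65	16	NA	NA
NADH1	PCG	-	5646	6578	NA	933	-47	ATA	TAA
DLOOP	other	+	6532	6618	NA	86	-33	NA	NA
trnL1	tRNA	-	6585	6655	tag	71	-29	NA	NA
rrnL	rRNA	-	6627	7972	NA	1346	27	NA	NA
trnV	tRNA	-	8000	8066	tac	67	-1	NA	NA
rrnS	rRNA	-	8066	8827	NA	762	57	NA	NA
CR	control	+	8885	10247	NA	1363	64	NA	NA
trnM	tRNA	+	10312	10379	cat	68	3	NA	NA
trnI	tRNA	+	10383	10449	gat	67	-3	NA	NA
trnQ	tRNA	-	10447	10515	ttg	69	59	NA	NA
NADH2	PCG	+	10575	11582	NA	1008	-2	ATT	TAA
trnW	tRNA	+	11581	11646	tca	66	-8	NA	NA
trnC	tRNA	-	11639	11701	gca	63	4	NA	NA
trnY	tRNA	-	11706	11772	gta	67	2	NA	NA
COI	PCG	+	11775	13316	NA	1542	-5	ATT	TAA
trnL2	tRNA	+	13312	13380	taa	69	0	NA	NA
COII	PCG	+	13381	14094	NA	714	-35	ATG	TAA
trnK	tRNA	+	14060	14130	ctt	71	-1	NA	NA
trnD	tRNA	+	14130	14197	gtc	68	0	NA	NA
ATP8	PCG	+	14198	14359	NA	162	-7	ATT	TAA
ATP6	PCG	+	14353	15030	NA	678	8	ATG	TAA
COIII	PCG	+	15039	15827	NA	789	2	ATG	TAA
trnG	tRNA	+	15830	15896	tcc	67	0	NA	NA
NADH3	PCG	+	15897	16250	NA	354	-2	ATT	TAG
trnA	tRNA	+	16249	16313	tgc	65	0	NA	NA
trnR	tRNA	+	16314	16376	tcg	63	4	NA	NA
trnN	tRNA	+	16381	41	gtt	68	0	NA	NA
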