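gene	strand	start	end	anticodon	start_codon	stop_codon
cox1	+	1	1536		ATA	TAA
nad3	+	1537	1890		ATG	TAA
cox2	+	1916	2584		ATA	TAA
trnD	+	2595	2661	GAC
trnR	+	2662	2723	CGA
trnG	+	2727	2788	GGA
trnK	+	2796	2858	AAA
cox3	+	2872	3702		ATA	TAA
trnN	+	3717	3782	AAC
trnE	+	3780	3842	GAA
trnI	+	3843	3909	ATC
cytb	+	3914	5014		ATT	TAA
trnY	-	5016	5079	TAC
nad2	+	5097	6087		ATC	T(AA)
trnW	+	6088	6152	TGA
nad1	+	6153	7089		ATA	T(AA)
trnM	+	7066	7126	ATG
trnF	+	7135	7206	TTC
rrnS	+	7213	7935
atp8	-	7937	8152		ATT	TAA
atp6	+	8166	8777		ATG	TAG
trnL1	+	8778	8841	CTA
trnT	+	8847	8906	ACA
trnQ	+	8906	8974	CAA
trnP	-	8985	9050	CCA
trnA	+	9059	9121	GCA
nad5	-	9132	10817		ATA	TAA
trnH	-	10818	10877	CAC
nad4	-	10880	12178		ATT	TAA
nad4L	-	12181	12459		ATG	TAA
CR2	+	12460	12759
trnV	+	12760	12819	GTA
CR1	+	12820	13447
nad6	+	13448	13918		ATT	TAA
rrnL	+	13920	15004
trnS1	+	15006	15069	TCA
trnC	+	15070	15129	TGC
trnL2	+	15130	15194	TTA
trnS2	+	15197	15254	AGA
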