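# Candidate lethal-haplotype summary from a screen of 62,022 genotyped
# Nellore animals (612,154 autosomal SNP, 3,073 segments of up to 200
# markers). One row per zero-homozygote haplotype retained by the screen:
# carrier (heterozygote) count, printed haplotype percentage, printed
# simple-method expected homozygote count and zero-homozygote probability,
# carrier-sire x carrier-MGS pair count, and printed mating-method
# probability. Counts are inputs; printed columns are the published values
# the package's arithmetic is checked against.
hap_id	bta	start_bp	end_bp	n_carriers	hap_pct	exp_hom_simple	phh_simple	n_matings	phh_mating
25.1	1	21773327	22571004	5929	4.78	141	4.07e-16	69	2.39e-09
108.7	1	92201954	93179359	4750	3.83	91	1.32e-10	123	4.29e-16
231.4	2	30989280	31660659	4998	4.03	101	1.15e-11	73	7.58e-10
346.2	2	125601735	126602788	11771	9.49	560	1.93e-61	368	1.05e-46
396.34	3	27103538	27639143	4291	3.46	74	8.65e-09	7	1.33e-01
461.4	3	84166546	84882788	5941	4.79	142	3.51e-16	96	1.01e-12
479.2	3	97862526	98537136	3783	3.05	57	5.43e-07	60	3.19e-08
676.135	5	19466593	20216556	4130	3.33	69	3.40e-08	2	5.63e-01
769.3	5	99424373	100174866	4143	3.34	69	3.07e-08	26	5.64e-04
966.2	7	19468345	20417099	6053	4.88	148	9.09e-17	58	5.67e-08
988.14	7	36554986	37251910	4329	3.49	76	6.26e-09	26	5.64e-04
1045.24	7	80932886	81622237	4564	3.68	84	7.57e-10	3	4.22e-01
1077.1	7	106846493	107525464	6958	5.61	196	6.29e-22	170	5.76e-22
1184.1	8	78277928	79262115	3832	3.09	59	3.71e-07	37	2.38e-05
1192.1	8	84943889	85809360	12441	10.03	625	1.48e-68	588	3.44e-74
1277.303	9	42710447	43514053	4056	3.27	66	6.29e-08	5	2.37e-01
1278.37	9	43515752	44346392	3733	3.01	56	7.91e-07	4	3.16e-01
1283.33	9	48144835	48978466	3981	3.21	63	1.15e-07	4	3.16e-01
1312.67	9	72521066	73292804	3721	3.00	56	8.68e-07	4	3.16e-01
1457.2	10	85722335	86530381	4378	3.53	77	4.05e-09	55	1.34e-07
1655.2	12	31305864	32200052	4242	3.42	72	1.33e-08	79	1.35e-10
2213.8	17	65952250	66468921	3696	2.98	55	1.05e-06	9	7.51e-02
2237.1	18	9785118	10380109	4775	3.85	92	1.04e-10	4	3.16e-01
2270.1	18	36265657	37406377	3795	3.06	58	4.94e-07	38	1.79e-05
2329.1	19	20292526	21133267	5358	4.32	116	2.69e-13	55	1.34e-07
2371.1	19	54651560	55237521	15145	12.21	927	2.63e-101	1028	3.66e-129
2585.3	22	18857788	19688790	4192	3.39	71	1.82e-08	78	1.80e-10
2620.2	22	46693982	47385511	4180	3.37	70	2.25e-08	10	5.63e-02
2724.2	24	18329342	19105911	4651	3.75	87	3.38e-10	76	3.20e-10
3063.3	29	40482004	41207696	6189	4.99	154	1.69e-17	163	4.32e-21
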