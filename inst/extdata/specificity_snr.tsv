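target	experiment	snr_ns	snr_s	p_value
B_fragilis_ATCC25285	1	0.85	30.81	9.35E-05
B_fragilis_ATCC25285	2	0.53	21.45	7.39E-04
B_thetaiotaomicron_ATCC29143	1	0.45	61.44	2.56E-04
B_thetaiotaomicron_ATCC29143	2	1.66	347.24	9.10E-06
L_gasseri_DSM20243	1	0.30	5.58	4.98E-03
L_gasseri_DSM20243	2	1.56	20.59	6.58E-03
P_melaninogenica_ATCC25845	1	1.54	480.24	6.02E-08
P_melaninogenica_ATCC25845	2	0.90	266.63	3.74E-09
B_subtilis_DSM704	1	7.93	637.39	1.56E-09
B_subtilis_DSM704	2	5.62	350.10	1.47E-05
E_coli_ATCC11105	1	3.27	555.04	8.65E-08
E_coli_ATCC11105	2	2.59	222.39	4.50E-07
P_mirabilis_DSM4479	1	2.42	703.22	7.74E-09
P_mirabilis_DSM4479	2	2.03	497.10	1.97E-09
B_bifidum_DSM20456	1	2.67	289.39	4.78E-11
B_bifidum_DSM20456	2	2.23	407.10	2.40E-08
L_casei_DSM20011	1	2.59	125.13	1.01E-04
L_casei_DSM20011	2	2.26	134.78	5.92E-04
Y_enterocolitica_faecal	1	1.53	231.33	1.01E-05
Y_enterocolitica_faecal	2	2.89	340.20	1.61E-06
B_cereus_DSM31	1	2.83	193.85	1.53E-06
B_cereus_DSM31	2	2.49	196.82	4.16E-03
B_adolescentis_ATCC15703	1	4.10	732.95	3.95E-10
B_adolescentis_ATCC15703	2	2.90	338.59	5.59E-07
L_rhamnosus_DSM20021	1	2.40	101.76	1.41E-03
L_rhamnosus_DSM20021	2	4.23	177.70	4.62E-07
L_delbrueckii_DSM20074	1	3.77	210.11	2.24E-08
L_delbrueckii_DSM20074	2	3.10	121.93	6.27E-08
L_pentosus_DSM20314	1	3.05	131.65	4.58E-09
L_pentosus_DSM20314	2	1.63	58.30	5.32E-07
L_acidophilus_DSM20079	1	2.39	68.49	8.70E-05
L_acidophilus_DSM20079	2	2.66	78.50	5.88E-06
L_reuteri_DSM20016	1	3.17	150.57	4.66E-09
L_reuteri_DSM20016	2	1.74	83.60	1.98E-07
L_plantarum_DSM21074	1	2.12	197.32	3.79E-09
L_plantarum_DSM21074	2	2.09	148.35	2.77E-08
C_difficile_ATCCBAA1382	1	1.12	238.87	4.88E-04
C_difficile_ATCCBAA1382	2	0.80	126.38	1.96E-03
C_jejuni_ATCC33292	1	0.70	19.89	5.29E-03
C_jejuni_ATCC33292	2	0.91	28.44	5.69E-03
V_parvula_ATCC10790	1	1.12	205.66	1.57E-04
V_parvula_ATCC10790	2	0.99	140.95	1.39E-04
B_breve_DSM20091	1	2.22	570.01	6.22E-05
B_breve_DSM20091	2	1.69	289.07	2.72E-04
B_longum_ATCC15707	1	1.76	341.94	1.64E-03
B_longum_ATCC15707	2	0.66	134.86	4.26E-02
R_productus_ATCC23340	1	0.64	4.21	1.41E-03
R_productus_ATCC23340	2	1.06	17.16	1.24E-06
L_salivarius_SV2	1	0.89	12.23	4.34E-04
L_salivarius_SV2	2	0.65	7.27	2.69E-05
E_faecalis_ATCC700802	1	3.12	306.51	1.09E-03
E_faecalis_ATCC700802	2	2.27	217.16	6.56E-03
C_leptum_DSM73	1	2.28	88.89	5.52E-07
C_leptum_DSM73	2	1.13	39.86	2.00E-07
R_albus_DSM20455	1	1.46	47.05	2.50E-07
R_albus_DSM20455	2	1.41	32.01	4.37E-06
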