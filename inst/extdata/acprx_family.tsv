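gene_name	accession	chromosome	genomic_location	orf	exon	aa	mw	pi
AcPRX1	Aco006655	LG01	22,942,404–22,945,339	978	3	325	34.76	4.98
AcPRX2	Aco021354	LG01	10,118,322–10,124,972	1,059	4	352	37.51	4.82
AcPRX3	Aco021355	LG01	10,152,822–10,159,776	1,062	5	353	37.99	5.44
AcPRX4	Aco021357	LG01	10,182,978–10,185,914	993	4	330	34.94	4.61
AcPRX5	Aco022453	LG01	5,181,655–5,183,616	1,014	2	337	35.61	6.59
AcPRX6	Aco000925	LG02	15,616,393–15,618,018	1,056	4	351	38.15	4.99
AcPRX7	Aco020478	LG02	9,486,642–9,488,956	990	4	329	35.53	4.69
AcPRX8	Aco020482	LG02	9,502,096–9,508,514	993	4	330	35.88	6.59
AcPRX9	Aco011877	LG03	13,191,903–13,199,186	2094	11	697	75.87	4.81
AcPRX10	Aco014075	LG03	128,210–129,408	966	2	321	34.88	6.71
AcPRX11	Aco014076	LG03	123,997–125,071	930	2	309	33.03	5.28
AcPRX12	Aco002056	LG04	5,183,006–5,187,859	996	4	331	36.44	8.69
AcPRX13	Aco002344	LG04	2,268,585–2,275,634	1752	6	583	62	7.16
AcPRX14	Aco011124	LG04	13,559,958–13,561,759	975	3	324	34.67	4.61
AcPRX15	Aco011125	LG04	13,553,572–13,555,336	936	4	311	33.34	6.52
AcPRX16	Aco011128	LG04	13,524,180–13,526,013	963	4	320	34.36	6.8
AcPRX17	Aco014948	LG04	10,852,102–10,854,365	867	5	288	30.39	9.21
AcPRX18	Aco021983	LG04	181,855–183,224	963	4	320	34.28	9.12
AcPRX19	Aco021984	LG04	190,356–192,628	993	2	330	36.14	9.28
AcPRX20	Aco023522	LG04	374,033–376,168	993	2	330	36.09	9.27
AcPRX21	Aco023523	LG04	381,622–383,417	987	3	328	35.15	9.18
AcPRX22	Aco004317	LG05	2,129,882–2,143,830	3,060	10	1,019	109.73	8.74
AcPRX23	Aco004613	LG05	4,458,890–4,468,179	1,467	7	488	52.01	6.06
AcPRX24	Aco004784	LG05	5,778,917–5,781,088	960	4	319	34.87	5.36
AcPRX25	Aco002775	LG06	11,491,541–11,493,377	1,068	3	355	39.02	5.2
AcPRX26	Aco002920	LG06	12,578,625–12,580,313	1,014	2	337	36.47	8.04
AcPRX27	Aco003045	LG06	13,446,497–13,448,722	999	4	332	36.19	4.99
AcPRX28	Aco021646	LG06	3,277,357–3,281,208	999	4	332	36.19	8.39
AcPRX29	Aco004906	LG07	711,110–714,125	987	4	328	34.98	6.8
AcPRX30	Aco014483	LG07	13,942,612–13,950,563	1971	14	656	73.27	5.57
AcPRX31	Aco014484	LG07	13,930,364–13,942,392	2,229	9	742	82.31	8.49
AcPRX32	Aco014486	LG07	13,917,358–13,919,006	987	4	328	36.41	7.06
AcPRX33	Aco016652	LG08	10,748,165–10,759,910	1989	8	662	70.55	4.87
AcPRX34	Aco022304	LG08	12,736,030–12,741,485	1,668	7	555	59.63	5.83
AcPRX35	Aco008544	LG09	630,761–632,783	990	4	329	35.57	5.06
AcPRX36	Aco008990	LG09	12,648,397–12,649,951	987	3	328	36.57	8.43
AcPRX37	Aco009079	LG09	13,183,005–13,184,814	1,026	3	341	37.16	4.9
AcPRX38	Aco015772	LG09	10,764,795–10,767,222	999	4	332	35.59	7.5
AcPRX39	Aco009743	LG10	64,021–70,344	1,521	7	506	55.56	9.17
AcPRX40	Aco010007	LG10	2,135,816–2,138,014	951	3	316	34.21	5.89
AcPRX41	Aco010009	LG10	2,138,049–2,158,166	2,760	11	919	98.4	7.93
AcPRX42	Aco020332	LG10	12,894,588–12,902,324	1,092	5	363	39.52	8.71
AcPRX43	Aco020334	LG10	12,882,382–12,885,182	1,044	4	347	38.36	5.17
AcPRX44	Aco005737	LG11	12,540,906–12,548,249	1,545	5	514	56.57	9.92
AcPRX45	Aco016519	LG11	383,223–387,691	1,011	4	336	36.65	8.08
AcPRX46	Aco012522	LG13	1,786,966–1,789,080	957	4	318	34.11	6.05
AcPRX47	Aco012524	LG13	1,805,368–1,809,238	960	4	319	34.05	8.09
AcPRX48	Aco013666	LG13	11,351,548–11,352,919	1,050	2	349	38.04	6.67
AcPRX49	Aco006432	LG14	2,360,239–2,362,650	999	4	332	35.12	4.61
AcPRX50	Aco014874	LG14	344,806–346,770	1,053	4	350	38.81	8.46
AcPRX51	Aco013384	LG15	10,676,947–10,698,878	2,886	12	961	103.55	5.97
AcPRX52	Aco006230	LG16	7,715,989–7,722,953	1,104	3	367	39.66	8.85
AcPRX53	Aco021127	LG16	508,904–513,657	969	4	322	34.98	8.33
AcPRX54	Aco026779	LG16	183,852–190,883	999	5	332	35.78	4.57
AcPRX55	Aco003198	LG17	1,062,168–1,065,621	1,083	3	360	38.62	8.47
AcPRX56	Aco003200	LG17	1,070,224–1,073,010	1,083	3	360	38.71	8.58
AcPRX57	Aco003320	LG17	1,983,887–1,985,624	1,002	4	333	36.02	5.1
AcPRX58	Aco001617	LG18	9,253,311–9,270,632	2,364	12	787	83.69	4.95
AcPRX59	Aco001618	LG18	9,248,026–9,252,038	1914	6	637	67.86	4.52
AcPRX60	Aco008430	LG19	10,318,327–10,320,385	1,020	4	339	38.22	8.53
AcPRX61	Aco008465	LG19	10,590,430–10,593,279	1,002	4	333	36.69	6.94
AcPRX62	Aco015271	LG20	10,156,870–10,159,414	1,068	2	355	37.94	8.92
AcPRX63	Aco019704	LG20	8,345,185–8,348,513	1,014	4	337	35.72	4.7
AcPRX64	Aco028441	LG20	8,837,469–8,839,195	303	2	100	11.33	9.96
AcPRX65	Aco009344	LG22	7,804,594–7,809,328	948	4	315	33.75	6.06
AcPRX66	Aco017479	LG22	1,177,709–1,189,266	3,174	9	1,057	118.18	5.84
AcPRX67	Aco007303	LG23	3,248,931–3,253,068	981	4	326	34.91	6.1
AcPRX68	Aco012993	LG25	1,550,545–1,551,925	975	4	324	35.04	6.07
AcPRX69	Aco012994	LG25	1,544,211–1,545,775	984	4	327	35.19	7.54
AcPRX70	Aco030748	scaffold_1315	7,476–13,988	1,059	4	352	37.48	4.73
AcPRX71	Aco028733	scaffold_1328	5,042–7,342	981	4	326	35.37	4.87
AcPRX72	Aco029135	scaffold_1464	25,017–29,639	1,227	3	408	43.69	6.23
AcPRX73	Aco029860	scaffold_1666	5,369–16,413	1758	8	585	63.71	8.93
AcPRX74	Aco027813	scaffold_1838	5,808–8,224	999	4	332	35.12	4.61
AcPRX75	Aco031666	scaffold_2216	6,898–8,468	966	3	321	34.55	7.07
AcPRX76	Aco029389	scaffold_2281	5,013–7,429	999	4	332	35.12	4.61
AcPRX77	Aco031596	scaffold_2950	101–3,231	693	3	230	25.96	9.4
AcPRX78	Aco025498	scaffold_691	13,170–16,131	1,056	3	351	38	10.28
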