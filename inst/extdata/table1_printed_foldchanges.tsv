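gene	fe_mean	fe_sd	pi_mean	pi_sd
AT3G12900	612.44	199.47	0.06	0.10
AT4G31940	184.70	3.63	0.08	0.01
AT1G52120	157.65	59.83	6.13	2.70
AT3G46900	71.15	33.39	0.40	0.36
AT1G01580	59.73	10.56	0.35	0.05
AT5G02780	57.98	10.87	0.69	0.06
AT4G19690	54.72	7.88	0.26	0.04
AT5G38820	54.35	11.69	0.43	0.09
AT3G56980	34.23	13.48	0.73	0.18
AT3G13610	10.04	0.65	1.63	0.25
AT1G73120	8.98	2.09	0.28	0.11
AT1G73220	17.38	6.18	196.69	139.63
AT4G33020	7.09	2.01	2.21	0.97
AT5G05250	6.62	0.95	0.57	0.10
AT3G61410	6.53	1.32	3.79	0.43
AT1G74770	6.43	0.50	0.66	0.07
AT5G19560	5.33	0.51	2.12	0.20
AT2G02310	5.30	2.01	0.49	0.12
AT2G33020	5.05	1.74	0.48	0.33
AT3G59880	4.58	2.42	2.51	0.54
AT5G01060	4.44	0.17	1.70	0.10
AT5G04950	4.39	0.50	0.49	0.01
AT3G57157	4.28	0.37	9.81	1.46
AT3G60330	4.27	0.69	1.79	0.21
AT3G21500	3.76	1.94	0.40	0.26
AT3G21240	3.73	0.16	1.25	0.09
AT3G50710	3.57	1.09	2.71	1.32
AT1G18910	3.33	0.13	0.78	0.04
AT5G48657	3.33	0.71	1.36	0.23
AT1G01380	3.22	1.09	3.73	1.22
AT1G51680	3.22	0.06	1.27	0.19
AT5G54790	3.20	0.75	2.02	0.19
AT2G01880	3.14	0.21	3.31	0.81
AT5G19970	2.81	0.43	0.57	0.07
AT5G65500	2.73	0.60	6.26	0.42
AT4G12735	2.67	1.20	1.87	0.47
AT3G57160	2.57	0.55	1.46	0.23
AT5G26820	2.54	0.28	0.77	0.19
AT4G30490	2.52	0.32	1.40	0.08
AT1G78230	2.51	0.57	0.59	0.22
AT3G18290	2.51	0.14	0.76	0.09
AT1G51870	2.42	0.42	2.25	0.83
AT5G22555	2.37	0.58	4.13	2.07
AT1G53310	2.34	0.19	2.21	0.25
AT3G51570	2.32	0.58	2.70	1.18
AT5G22890	2.32	0.53	1.91	0.25
AT4G22980	2.30	0.28	0.56	0.14
AT1G14190	2.29	0.41	0.78	0.08
AT1G48300	2.27	0.25	0.85	0.07
AT1G24320	2.26	0.27	0.78	0.09
AT1G62422	2.25	0.43	1.37	0.10
AT4G38950	2.25	0.45	1.50	0.15
AT3G47420	2.24	0.27	12.82	5.53
AT5G26320	2.24	0.26	2.95	0.37
AT2G43570	2.22	0.87	2.26	0.45
AT4G26890	2.16	0.42	3.00	0.85
AT5G13910	2.14	0.15	1.25	0.16
AT5G27920	2.14	0.15	1.29	0.15
AT3G15510	2.13	0.62	0.71	0.15
AT5G53850	2.09	0.06	0.96	0.01
AT2G18193	2.07	0.26	1.29	0.01
AT2G32960	2.07	0.23	4.79	1.23
AT1G64590	2.06	0.13	2.39	0.70
AT5G48930	2.04	0.17	1.16	0.07
AT2G14210	2.01	0.37	0.82	0.09
AT5G20790	0.32	0.13	90.27	24.26
AT1G30560	-	-	55.93	32.45
AT5G01220	0.86	0.06	10.49	3.02
AT1G72070	1.72	0.62	6.60	3.34
AT3G52720	10.40	0.20	5.56	3.11
AT1G23140	1.58	0.43	5.33	1.19
AT3G52190	1.22	0.12	5.25	0.61
AT3G56040	0.74	0.18	4.98	0.71
AT3G02870	0.79	0.06	4.64	0.29
AT3G16390	0.67	0.08	4.55	0.59
AT3G07350	0.54	0.07	4.40	0.09
AT3G19970	1.58	0.08	4.37	0.76
AT1G15040	0.60	0.04	3.73	1.12
AT3G12500	0.52	0.05	3.05	0.75
AT1G18970	0.71	0.12	3.04	0.41
AT2G29000	1.85	0.60	3.03	0.79
AT3G53620	0.82	0.03	2.96	0.19
AT1G14220	0.74	0.18	2.89	0.27
AT4G32480	1.35	0.19	2.85	1.36
AT3G06962	1.82	0.49	2.74	0.44
AT1G11920	-	-	2.68	0.51
AT1G08650	1.77	0.16	2.58	0.21
AT4G04040	0.83	0.04	2.50	0.22
AT5G57540	1.53	0.11	2.33	0.36
AT5G40860	1.51	0.11	2.32	0.81
AT1G68740	0.39	0.08	2.31	0.44
AT3G32040	1.32	0.21	2.30	0.11
AT2G25240	1.53	0.15	2.27	0.08
AT2G16430	0.68	0.08	2.26	0.33
AT4G30670	1.61	0.16	2.22	0.17
AT3G10420	1.24	0.08	2.20	0.35
AT2G42600	0.77	0.05	2.18	0.09
AT4G11650	0.67	0.10	2.16	0.38
AT2G23960	1.55	0.27	2.13	0.21
AT1G05300	0.49	0.05	2.13	0.11
AT3G13110	0.83	0.08	2.12	0.22
AT2G22290	1.91	0.66	2.10	0.59
AT4G20160	1.71	0.10	2.07	0.17
AT1G20390	0.56	0.11	2.07	0.04
AT5G20280	0.77	0.06	2.05	0.17
AT5G01870	0.71	0.10	2.05	0.51
AT3G05858	1.64	0.09	2.01	0.47
AT2G17280	1.16	0.02	2.01	0.47
AT1G26250	0.55	0.16	2.00	0.82
AT4G09110	-	-	0.77	0.04
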