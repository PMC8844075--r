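# Generic (Ballesteros-Weinstein) numbering for Y1R helices 2-7, derived
# arithmetically from published residue/generic-number correspondences
# (2.61=T97, 3.32=Q120, 4.60=F173, 5.46=Q219, 6.48=W276, 7.39=H306).
# TM1 is omitted (no published anchor).
chain	resno	bw
A	74	2.38
A	75	2.39
A	76	2.40
A	77	2.41
A	78	2.42
A	79	2.43
A	80	2.44
A	81	2.45
A	82	2.46
A	83	2.47
A	84	2.48
A	85	2.49
A	86	2.50
A	87	2.51
A	88	2.52
A	89	2.53
A	90	2.54
A	91	2.55
A	92	2.56
A	93	2.57
A	94	2.58
A	95	2.59
A	96	2.60
A	97	2.61
A	98	2.62
A	99	2.63
A	100	2.64
A	101	2.65
A	102	2.66
A	110	3.22
A	111	3.23
A	112	3.24
A	113	3.25
A	114	3.26
A	115	3.27
A	116	3.28
A	117	3.29
A	118	3.30
A	119	3.31
A	120	3.32
A	121	3.33
A	122	3.34
A	123	3.35
A	124	3.36
A	125	3.37
A	126	3.38
A	127	3.39
A	128	3.40
A	129	3.41
A	130	3.42
A	131	3.43
A	132	3.44
A	133	3.45
A	134	3.46
A	135	3.47
A	136	3.48
A	137	3.49
A	138	3.50
A	139	3.51
A	140	3.52
A	141	3.53
A	142	3.54
A	143	3.55
A	150	4.37
A	151	4.38
A	152	4.39
A	153	4.40
A	154	4.41
A	155	4.42
A	156	4.43
A	157	4.44
A	158	4.45
A	159	4.46
A	160	4.47
A	161	4.48
A	162	4.49
A	163	4.50
A	164	4.51
A	165	4.52
A	166	4.53
A	167	4.54
A	168	4.55
A	169	4.56
A	170	4.57
A	171	4.58
A	172	4.59
A	173	4.60
A	174	4.61
A	175	4.62
A	176	4.63
A	177	4.64
A	178	4.65
A	179	4.66
A	180	4.67
A	205	5.32
A	206	5.33
A	207	5.34
A	208	5.35
A	209	5.36
A	210	5.37
A	211	5.38
A	212	5.39
A	213	5.40
A	214	5.41
A	215	5.42
A	216	5.43
A	217	5.44
A	218	5.45
A	219	5.46
A	220	5.47
A	221	5.48
A	222	5.49
A	223	5.50
A	224	5.51
A	225	5.52
A	226	5.53
A	227	5.54
A	228	5.55
A	229	5.56
A	230	5.57
A	231	5.58
A	232	5.59
A	233	5.60
A	234	5.61
A	235	5.62
A	236	5.63
A	237	5.64
A	238	5.65
A	239	5.66
A	240	5.67
A	256	6.28
A	257	6.29
A	258	6.30
A	259	6.31
A	260	6.32
A	261	6.33
A	262	6.34
A	263	6.35
A	264	6.36
A	265	6.37
A	266	6.38
A	267	6.39
A	268	6.40
A	269	6.41
A	270	6.42
A	271	6.43
A	272	6.44
A	273	6.45
A	274	6.46
A	275	6.47
A	276	6.48
A	277	6.49
A	278	6.50
A	279	6.51
A	280	6.52
A	281	6.53
A	282	6.54
A	283	6.55
A	284	6.56
A	285	6.57
A	286	6.58
A	287	6.59
A	288	6.60
A	289	6.61
A	290	6.62
A	291	6.63
A	296	7.29
A	297	7.30
A	298	7.31
A	299	7.32
A	300	7.33
A	301	7.34
A	302	7.35
A	303	7.36
A	304	7.37
A	305	7.38
A	306	7.39
A	307	7.40
A	308	7.41
A	309	7.42
A	310	7.43
A	311	7.44
A	312	7.45
A	313	7.46
A	314	7.47
A	315	7.48
A	316	7.49
A	317	7.50
A	318	7.51
A	319	7.52
A	320	7.53
A	321	7.54
A	322	7.55
A	323	7.56
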