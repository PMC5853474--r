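gene_id	young_1	young_2	young_3	expanded_1	expanded_2	expanded_3
g0001	80	90	98	224	240	219
g0002	181	171	88	68	70	48
g0003	37	58	71	1904	1146	961
g0004	151	114	122	120	137	87
g0005	124	103	218	10	11	23
g0006	275	202	260	193	240	308
g0007	200	130	134	172	144	114
g0008	146	80	83	182	109	91
g0009	306	183	146	1043	1712	1473
g0010	98	85	60	162	347	185
g0011	111	135	243	146	143	178
g0012	43	53	64	12	8	7
g0013	237	159	401	109	94	107
g0014	31	46	25	31	39	34
g0015	113	68	98	68	81	73
g0016	80	83	57	163	152	298
g0017	59	47	42	442	461	487
g0018	64	107	178	74	135	68
g0019	45	42	24	54	43	58
g0020	19	18	17	7	8	6
g0021	92	90	95	66	102	76
g0022	125	166	170	634	460	365
g0023	66	76	137	108	82	49
g0024	31	34	37	41	59	32
g0025	182	221	155	153	142	205
g0026	37	33	25	55	35	18
g0027	96	107	162	101	144	155
g0028	93	126	102	106	91	97
g0029	178	222	121	339	352	497
g0030	140	154	127	855	1073	835
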