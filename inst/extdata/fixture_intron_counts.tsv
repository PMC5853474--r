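gene_id	young_1	young_2	young_3	expanded_1	expanded_2	expanded_3
g0001	10	11	9	16	22	22
g0002	17	14	15	5	1	8
g0003	6	6	10	26	32	24
g0004	12	17	17	18	6	14
g0005	12	17	13	12	7	12
g0006	42	21	27	16	44	47
g0007	19	14	23	14	15	39
g0008	14	10	17	14	22	13
g0009	29	19	28	32	21	33
g0010	8	8	12	33	49	24
g0011	10	19	9	22	19	14
g0012	10	8	16	10	6	11
g0013	42	13	39	11	22	7
g0014	5	3	5	12	6	8
g0015	11	9	13	5	10	22
g0016	17	16	11	22	22	25
g0017	9	2	4	8	6	12
g0018	16	9	19	14	6	23
g0019	16	11	13	11	9	10
g0020	1	3	6	1	0	1
g0021	13	20	8	10	10	12
g0022	28	24	34	47	85	67
g0023	6	7	8	9	14	15
g0024	5	2	3	3	0	5
g0025	12	35	19	35	23	17
g0026	7	6	4	4	7	6
g0027	11	14	13	4	6	30
g0028	19	8	18	12	13	6
g0029	21	14	14	39	57	34
g0030	9	9	12	18	16	10
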