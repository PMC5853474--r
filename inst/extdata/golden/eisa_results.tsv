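gene_id	delta_exon	delta_intron	delta_diff	p_value	fdr	call	direction
g0001	0.19208515	0.3913325	-0.19924735	0.44093918	0.51762426	not_called	down
g0003	3.3118959	0.98347784	2.3284181	0.00092711217	0.0062580072	post_transcriptional	up
g0004	-1.2550245	-0.44178206	-0.81324243	0.20592673	0.29263272	not_called	down
g0005	-3.6865604	-0.49333938	-3.1932211	1.2076519e-09	3.2606601e-08	post_transcriptional	down
g0006	-1.1207679	-0.15233681	-0.96843107	0.039137687	0.073431966	not_called	down
g0007	-1.1901866	-0.14014134	-1.0500453	0.022763623	0.056004515	not_called	down
g0008	-0.79594273	-0.073724093	-0.72221864	0.16820419	0.25230628	not_called	down
g0009	1.6002953	-0.14559589	1.7458912	0.0003395907	0.0030563163	post_transcriptional	up
g0010	0.29284235	1.0463336	-0.75349124	0.023432507	0.056004515	not_called	down
g0011	-1.08923	0.12576862	-1.2149986	0.011179103	0.041258033	post_transcriptional	down
g0012	-2.6862994	-0.37437419	-2.3119252	2.4672738e-06	3.3308197e-05	post_transcriptional	down
g0013	-2.2958979	-1.0861145	-1.2097834	0.077925993	0.12376481	not_called	down
g0014	-0.8915084	0.2781899	-1.1696983	0.0080611708	0.036275269	post_transcriptional	down
g0015	-1.3295111	-0.2061344	-1.1233768	0.026965137	0.056004515	not_called	down
g0016	0.26327712	0.20066771	0.062609413	0.9005545	0.9005545	not_called	up
g0017	1.9866982	0.23094436	1.7557539	0.012224602	0.041258033	post_transcriptional	up
g0018	-1.3275376	-0.29133377	-1.0362039	0.043515239	0.073431966	not_called	down
g0019	-0.54001212	-0.45557483	-0.084437297	0.85530274	0.888199	not_called	down
g0021	-1.2451865	-0.41000917	-0.8351773	0.29628146	0.38093331	not_called	down
g0022	0.47429599	0.68583807	-0.21154208	0.48636154	0.52527046	not_called	down
g0023	-1.2508841	0.24797831	-1.4988624	0.0017355123	0.0093717664	post_transcriptional	down
g0025	-1.2567819	-0.098679337	-1.1581026	0.026327994	0.056004515	not_called	down
g0026	-0.86064876	-0.16057431	-0.70007445	0.37992287	0.46626898	not_called	down
g0027	-0.9468076	-0.38384394	-0.56296367	0.21824145	0.29462595	not_called	down
g0028	-1.1811731	-0.51747991	-0.66369322	0.47414721	0.52527046	not_called	down
g0029	0.057083282	0.78715472	-0.73007144	0.042774083	0.073431966	not_called	down
g0030	1.5248779	0.10489236	1.4199855	0.014644669	0.043934007	post_transcriptional	up
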