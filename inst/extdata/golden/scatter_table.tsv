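gene_id	delta_intron	delta_exon	call
g0001	0.3913325	0.19208515	not_called
g0003	0.98347784	3.3118959	post_transcriptional
g0004	-0.44178206	-1.2550245	not_called
g0005	-0.49333938	-3.6865604	post_transcriptional
g0006	-0.15233681	-1.1207679	not_called
g0007	-0.14014134	-1.1901866	not_called
g0008	-0.073724093	-0.79594273	not_called
g0009	-0.14559589	1.6002953	post_transcriptional
g0010	1.0463336	0.29284235	not_called
g0011	0.12576862	-1.08923	post_transcriptional
g0012	-0.37437419	-2.6862994	post_transcriptional
g0013	-1.0861145	-2.2958979	not_called
g0014	0.2781899	-0.8915084	post_transcriptional
g0015	-0.2061344	-1.3295111	not_called
g0016	0.20066771	0.26327712	not_called
g0017	0.23094436	1.9866982	post_transcriptional
g0018	-0.29133377	-1.3275376	not_called
g0019	-0.45557483	-0.54001212	not_called
g0021	-0.41000917	-1.2451865	not_called
g0022	0.68583807	0.47429599	not_called
g0023	0.24797831	-1.2508841	post_transcriptional
g0025	-0.098679337	-1.2567819	not_called
g0026	-0.16057431	-0.86064876	not_called
g0027	-0.38384394	-0.9468076	not_called
g0028	-0.51747991	-1.1811731	not_called
g0029	0.78715472	0.057083282	not_called
g0030	0.10489236	1.5248779	post_transcriptional
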