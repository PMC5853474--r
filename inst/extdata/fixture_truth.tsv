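gene_id	class	t_i	p_i
g0001	transcriptional	1.5	0
g0002	transcriptional	-1.5	0
g0003	both	1.5	3
g0004	null	0	0
g0005	post_transcriptional	0	-3
g0006	null	0	0
g0007	null	0	0
g0008	null	0	0
g0009	post_transcriptional	0	3
g0010	transcriptional	1.5	0
g0011	null	0	0
g0012	post_transcriptional	0	-3
g0013	transcriptional	-1.5	0
g0014	null	0	0
g0015	null	0	0
g0016	transcriptional	1.5	0
g0017	post_transcriptional	0	3
g0018	null	0	0
g0019	null	0	0
g0020	transcriptional	-1.5	0
g0021	null	0	0
g0022	transcriptional	1.5	0
g0023	null	0	0
g0024	null	0	0
g0025	null	0	0
g0026	null	0	0
g0027	null	0	0
g0028	null	0	0
g0029	transcriptional	1.5	0
g0030	post_transcriptional	0	3
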