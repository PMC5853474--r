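gene_id	log2_fc	ppde	call
g0001	0.97192658	1	not_de
g0003	4.2016721	0.99999998	up_in_expanded
g0004	-0.53746094	0.8483987	not_de
g0005	-3.6586912	0.99999749	up_in_young
g0006	-0.36006098	0.33944827	not_de
g0007	-0.47850126	0.46469441	not_de
g0008	-0.064911813	0.1668485	not_de
g0009	2.3692177	0.99999972	up_in_expanded
g0010	1.1436426	0.63287335	not_de
g0011	-0.44048689	0.22515175	not_de
g0012	-2.8693989	1	up_in_young
g0013	-1.7288205	0.9192983	not_de
g0014	-0.34295224	0.28191901	not_de
g0015	-0.69274091	0.91491003	not_de
g0016	1.1007245	0.73758676	not_de
g0017	2.8500684	1	up_in_expanded
g0018	-0.7036199	0.31009333	not_de
g0019	0.10709929	0.16410042	not_de
g0021	-0.54999395	0.95753677	not_de
g0022	1.2804035	0.99432245	up_in_expanded
g0023	-0.59796422	0.32814466	not_de
g0025	-0.53219649	0.6535631	not_de
g0026	-0.18888675	0.24467955	not_de
g0027	-0.23913944	0.19301269	not_de
g0028	-0.50192163	0.84234448	not_de
g0029	0.81272404	0.82028593	not_de
g0030	2.337947	1	up_in_expanded
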