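g0001	sp2_g0001
g0002	sp2_g0002
g0003	sp2_g0003
g0004	sp2_g0004
g0005	sp2_g0005
g0006	sp2_g0006
g0007	sp2_g0007
g0008	sp2_g0008
g0009	sp2_g0009
g0010	sp2_g0010
g0011	sp2_g0011
g0012	sp2_g0012
g0013	sp2_g0013
g0014	sp2_g0014
g0015	sp2_g0015
g0016	sp2_g0016
g0017	sp2_g0017
g0018	sp2_g0018
g0019	sp2_g0019
g0020	sp2_g0020
g0021	sp2_g0021
g0022	sp2_g0022
g0023	sp2_g0023
g0024	sp2_g0024
g0025	sp2_g0025
g0026	sp2_g0026
g0027	sp2_g0027
g0028	sp2_g0028
g0029	sp2_g0029
g0030	sp2_g0030
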