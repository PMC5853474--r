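gene_id	category_id	category_name
g0003	CAT:PT	mRNA stability pathway
g0005	CAT:PT	mRNA stability pathway
g0009	CAT:PT	mRNA stability pathway
g0012	CAT:PT	mRNA stability pathway
g0017	CAT:PT	mRNA stability pathway
g0030	CAT:PT	mRNA stability pathway
g0014	CAT:PT	mRNA stability pathway
g0024	CAT:PT	mRNA stability pathway
g0010	CAT:BG	background process
g0002	CAT:BG	background process
g0020	CAT:BG	background process
g0011	CAT:BG	background process
g0004	CAT:BG	background process
g0026	CAT:BG	background process
g0027	CAT:BG	background process
g0024	CAT:BG	background process
g0015	CAT:BG	background process
g0014	CAT:BG	background process
g0016	CAT:BG	background process
g0025	CAT:BG	background process
g0006	CAT:BG	background process
g0022	CAT:BG	background process
g0028	CAT:BG	background process
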