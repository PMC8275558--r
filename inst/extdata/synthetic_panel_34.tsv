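rsID	risk_allele	other_allele	weight	raf	population	gene
rs10906115	G	A	0.248	0.598	East Asian	CDC123/CAMK1D
rs7172432	C	G	0.237	0.263	East Asian	C2CD4B/NPM1P47
rs35612982	A	T	0.113	0.154	East Asian	CDKAL1
rs1801282	T	C	0.051	0.778	European	PPARG
rs340874	A	T	0.079	0.748	Multi-ethnic	PROX1
rs9936385	C	T	0.242	0.275	Multi-ethnic	FTO
rs13266634	T	C	0.269	0.192	European	SLC30A8
rs7612463	G	A	0.25	0.832	Multi-ethnic	UBE2E2
rs6815464	G	A	0.142	0.589	East Asian	MAEA
rs780094	A	T	0.283	0.619	European	GCKR
rs231362	G	T	0.17	0.409	European	KCNQ1
rs10811661	C	G	0.121	0.472	European	CDKN2A/B
rs1552224	T	C	0.068	0.845	European	CENTD2
rs243021	C	A	0.121	0.659	European	BCL11
rs2237892	C	T	0.073	0.488	East Asian	KCNQ1
rs2191349	T	G	0.153	0.653	Multi-ethnic	DGKB
rs5215	C	T	0.297	0.716	European	KCNJ11
rs4430796	T	G	0.297	0.555	European	TCF2/HNF1B
rs4402960	T	C	0.244	0.475	European	IGF2BP2
rs896854	T	G	0.198	0.423	European	TP53INP1
rs2943641	C	T	0.047	0.747	European	IRS1
rs1359790	A	C	0.148	0.718	East Asian	SPRY2
rs1111875	C	T	0.178	0.672	European	HHEX/IDE
rs7903146	C	G	0.141	0.345	European	TCF7L2
rsS0000001	A	C	0.297	0.38	East Asian	SYNTHETIC
rsS0000002	C	T	0.314	0.681	East Asian	SYNTHETIC
rsS0000003	G	C	0.112	0.231	East Asian	SYNTHETIC
rsS0000004	C	G	0.051	0.856	East Asian	SYNTHETIC
rsS0000005	T	G	0.238	0.343	East Asian	SYNTHETIC
rsS0000006	C	G	0.273	0.184	East Asian	SYNTHETIC
rsS0000007	T	G	0.11	0.325	East Asian	SYNTHETIC
rsS0000008	C	T	0.305	0.19	East Asian	SYNTHETIC
rsS0000009	G	C	0.057	0.84	East Asian	SYNTHETIC
rsS0000010	A	C	0.204	0.685	East Asian	SYNTHETIC
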