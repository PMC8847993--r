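MITOTIC_PROGRESSION	example	KIN0001	KIN0002	KIN0003	KIN0004	KIN0005	KIN0006	KIN0007	KIN0008	KIN0009	KIN0010	KIN0011	KIN0012	KIN0013	KIN0014	KIN0015	KIN0016	KIN0017	KIN0018	KIN0019	KIN0020
DNA_REPAIR	example	KIN0011	KIN0012	KIN0013	KIN0014	KIN0015	KIN0016	KIN0017	KIN0018	KIN0019	KIN0020	KIN0021	KIN0022	KIN0023	KIN0024	KIN0025	KIN0026	KIN0027	KIN0028	KIN0029	KIN0030	KIN0031	KIN0032	KIN0033	KIN0034	KIN0035
SPINDLE_CHECKPOINT	example	KIN0030	KIN0031	KIN0032	KIN0033	KIN0034	KIN0035	KIN0036	KIN0037	KIN0038	KIN0039	KIN0040	KIN0041	KIN0042	KIN0043	KIN0044	KIN0045
METABOLIC_KINASES	example	KIN0046	KIN0047	KIN0048	KIN0049	KIN0050	KIN0051	KIN0052	KIN0053	KIN0054	KIN0055	KIN0056	KIN0057	KIN0058	KIN0059	KIN0060	KIN0061	KIN0062	KIN0063	KIN0064	KIN0065	KIN0066	KIN0067	KIN0068	KIN0069	KIN0070	KIN0071	KIN0072	KIN0073	KIN0074	KIN0075	KIN0076	KIN0077	KIN0078	KIN0079	KIN0080
CYTOKINESIS	example	KIN0001	KIN0002	KIN0003	KIN0004	KIN0005	KIN0006	KIN0007	KIN0008	KIN0009	KIN0010	KIN0081	KIN0082	KIN0083	KIN0084	KIN0085	KIN0086	KIN0087	KIN0088	KIN0089	KIN0090
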