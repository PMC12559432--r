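sample_id	cluster	grading	intervention	prediction	Merkel cell carcinoma	Appendiceal NEN	Colorectal NEN	Gastric/duodenal NEN	Ileal NEN	Pancreatic NEN	Pulmonary NEC	Pulmonary carcinoid
Patient #038	2	NET G2	Bx	NEN ileum	0.022	0.055	0.040	0.065	0.627	0.123	0.015	0.054
Patient #018	2	NET G2	Bx	NEN ileum	0.028	0.073	0.073	0.119	0.427	0.166	0.019	0.095
Patient #035	1	SCNEC	Bx	NEN colorectal	0.073	0.041	0.507	0.097	0.020	0.035	0.201	0.027
Patient #032	1	NET G3	Bx	NEN colorectal	0.043	0.034	0.375	0.168	0.051	0.115	0.171	0.043
Patient #036	1	LCNEC	Bx	NEN colorectal	0.053	0.041	0.331	0.174	0.053	0.091	0.215	0.041
Patient #037	1	LCNEC	Bx	NEN colorectal	0.043	0.055	0.305	0.219	0.099	0.094	0.150	0.034
Patient #030	1	NET G3	Rx	NEN colorectal	0.038	0.094	0.220	0.199	0.141	0.135	0.125	0.048
Patient #029	1	SCNEC	Rx	Pulmonary NEC	0.087	0.035	0.083	0.067	0.006	0.025	0.666	0.032
Patient #017	1	LCNEC	Bx	Pulmonary NEC	0.043	0.029	0.178	0.077	0.008	0.028	0.600	0.037
Patient #026	1	LCNEC	Bx	Pulmonary NEC	0.101	0.045	0.172	0.086	0.021	0.041	0.493	0.042
Patient #025	1	LCNEC	Bx	Pulmonary NEC	0.187	0.050	0.161	0.109	0.010	0.035	0.414	0.034
Patient #028	1	LCNEC	Bx	Pulmonary NEC	0.039	0.061	0.239	0.125	0.019	0.069	0.395	0.053
Patient #016	1	NET G2	Bx	Pulmonary NEC	0.163	0.042	0.133	0.123	0.040	0.065	0.366	0.068
Patient #031	1	LCNEC	Bx	Pulmonary NEC	0.231	0.081	0.179	0.107	0.013	0.035	0.321	0.033
Patient #034	1	LCNEC	Rx	Pulmonary NEC	0.204	0.069	0.141	0.158	0.016	0.061	0.290	0.060
Patient #013	2	NET G2	Rx	NEN pancreas	0.018	0.040	0.059	0.232	0.080	0.395	0.050	0.127
Patient #033	2	NET G1	Rx	NEN pancreas	0.037	0.046	0.067	0.179	0.158	0.343	0.061	0.109
Patient #015	2	NET G2	Bx	NEN pancreas	0.035	0.033	0.052	0.135	0.136	0.336	0.029	0.245
Patient #039	2	NET G1	Rx	NEN pancreas	0.021	0.055	0.045	0.300	0.088	0.305	0.057	0.131
Patient #021	1	LCNEC	Bx	NEN pancreas	0.089	0.060	0.127	0.187	0.163	0.207	0.094	0.073
Patient #020	2	NET G1	Rx	NEN gastric/duodenal	0.020	0.146	0.223	0.231	0.081	0.164	0.079	0.056
Patient #014	1	NET G3	Bx	NEN gastric/duodenal	0.070	0.040	0.138	0.227	0.086	0.158	0.215	0.066
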