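left_start	left_end	right_start	right_end	repeat_length	mismatch_rate	spacer	recombinogenic
3801595	3801626	3801662	3801693	32	0.031	35	no
3808004	3808036	3809074	3809108	33	0.121	1037	no
3809309	3809356	3809684	3809731	48	0.083	327	no
3809775	3809812	3810283	3810317	35	0.142	470	no
3809920	3809972	3810588	3810640	53	0.056	615	no
3812968	3813016	3813948	3813994	47	0.148	931	no
3834774	3834814	3835410	3835450	41	0.024	595	no
3861385	3861419	3863345	3863379	35	0.085	1925	no
3868611	3868644	3869190	3869223	34	0.058	545	no
3880525	3880559	3880580	3880614	35	0	20	yes
3892447	3892480	3894367	3894400	34	0.088	1886	no
3894385	3894435	3894952	3895002	51	0.058	516	no
3903431	3903467	3903482	3903518	37	0	14	yes
3906855	3906912	3908736	3908793	58	0.068	1823	no
3970674	3970704	3971538	3971568	31	0.096	833	no
3979626	3979672	3979822	3979866	45	0.133	149	no
3989493	3989614	3990425	3990548	122	0.047	811	no
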