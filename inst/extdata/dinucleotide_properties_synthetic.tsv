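oligo	DP01	DP02	DP03	DP04	DP05	DP06	DP07	DP08	DP09	DP10	DP11	DP12	DP13	DP14	DP15
AA	0.3586	-0.6621	1.2546	-0.3214	-0.5742	-0.0019	0.4081	0.7353	0.1745	-0.1098	0.1571	-0.3588	0.4383	0.9731	-0.5984
AC	0.9558	0.9213	0.5797	1.3316	2.387	1.4655	0.7986	1.4858	-0.9684	-1.4023	-0.0967	0.5915	-0.878	-0.4707	-1.1856
AG	-1.1882	1.0293	-0.066	-0.5317	-1.7153	-1.137	-1.1227	1.1877	1.1863	1.7553	1.634	-0.813	-0.3485	1.3333	-0.0995
AT	0.0508	-0.4668	0.165	-0.6824	-0.0784	-0.5109	0.6018	-0.2214	0.7816	-0.061	-1.6673	-0.6794	-0.1507	0.4838	0.3194
CA	0.5101	-0.3124	-1.4143	0.9399	0.2717	-0.9375	0.2252	-0.6771	0.114	0.9806	-0.8679	0.5321	0.8625	-0.8371	-0.0576
CC	0.4633	0.2265	1.7246	-0.7542	0.9532	-1.3123	-0.3957	-0.9343	0.6639	0.6083	0.2051	0.7384	2.1226	0.616	0.887
CG	0.7346	-0.5615	1.1976	0.1531	0.0879	0.0674	1.4161	0.0741	-0.1249	0.0877	-0.192	-0.587	0.6305	0.9755	-0.5231
CT	0.0132	0.6526	-0.399	0.9943	0.5361	-0.6329	-1.187	-0.6529	0.1459	-0.7295	0.6966	-0.7192	-0.1628	-1.5921	2.4289
GA	-0.39	-0.3001	-0.6354	-1.2129	0.3807	-0.6382	-0.6176	1.1754	-0.1596	-1.1852	0.5373	-0.8056	-1.5881	0.6932	-0.99
GC	-1.0142	1.868	0.39	0.104	-0.8669	1.2312	-1.845	-0.2881	-0.4832	0.6678	0.6327	-1.5169	1.0254	-1.1954	0.3171
GG	-1.3422	0.1369	-0.756	1.1336	-0.2199	0.2049	0.6074	-1.0942	-0.9969	-0.8852	-0.266	1.9168	-0.9228	0.5608	1.7587
GT	-1.2966	-2.0507	-1.819	0.1563	-0.8865	-1.5337	1.4398	-0.279	0.132	1.4718	1.9444	-1.4753	-0.138	-0.163	-1.1657
TA	-0.9972	0.0818	1.0195	-0.0657	0.1105	1.4264	-0.7726	-1.2165	-1.3789	0.7456	-0.77	0.3014	0.2367	-1.5962	-0.1725
TC	0.4474	1.069	-0.9752	0.6588	0.6201	1.0995	0.1684	1.9724	-1.5074	-1.0143	-1.2082	1.1205	-0.8092	1.248	-0.7569
TG	2.3573	-0.0218	-0.0143	-2.5121	-1.531	0.6149	1.1527	-0.8744	2.4652	-1.2547	-1.1858	0.9814	1.0687	-0.9435	-0.1619
TT	0.3372	-1.6099	-0.2517	0.6089	0.525	0.5944	-0.8775	-0.3928	-0.0443	0.3251	0.4465	0.7733	-1.3865	-0.0859	0
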