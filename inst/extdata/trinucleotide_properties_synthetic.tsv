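oligo	TP01	TP02	TP03	TP04	TP05	TP06	TP07	TP08	TP09	TP10	TP11	TP12
AAA	-0.7026	-0.0816	2.018	-1.598	-0.4807	-0.8326	1.3421	0.8089	0.109	0.6338	-0.4225	-2.164
AAC	-0.7005	0.2576	0.2046	-0.7237	0.5701	0.3812	-0.2269	-1.2607	-0.4	0.5249	0.6666	0.6689
AAG	-0.7713	-1.1584	-1.7055	-1.7988	-0.8158	0.714	0.6415	0.8325	0.6995	0.2313	-1.5503	-0.7323
AAT	2.4088	-1.3514	-0.783	0.2358	0.9741	1.3471	0.3937	-1.1826	-0.6736	0.3601	0.3748	-0.1511
ACA	-1.9944	-0.6537	-1.503	-0.1904	-0.7678	1.2185	-1.6666	0.0232	-0.061	0.0098	0.7031	-0.9047
ACC	-0.2387	1.6088	0.3702	0.2776	-0.9932	-0.6728	0.012	-0.4825	0.8503	-0.6668	-2.0339	-0.255
ACG	-0.8705	-0.4642	0.1975	-0.6184	0.4849	-1.5621	1.8076	0.0764	0.0266	-0.6202	1.4035	1.4863
ACT	-0.5961	0.1301	-1.1079	-0.9796	0.4406	0.3239	-0.4439	1.428	-0.6265	0.7816	-0.5105	1.5311
AGA	0.2407	-0.4348	-0.4747	-0.5475	0.817	-1.4895	0.3809	-0.2066	-0.9003	-0.811	-0.5161	-0.123
AGC	-0.4995	0.8421	0.7211	-0.2811	-1.3515	0.9541	-0.0591	0.8413	1.2652	1.6645	-0.1463	-1.3094
AGG	1.7442	-1.0145	-0.6999	-0.1278	-0.5324	0.4555	-0.0423	0.4296	-2.5714	-0.5326	-1.1051	0.132
AGT	1.3578	1.2279	0.1354	1.3907	0.0177	-0.215	-0.7868	0.0913	-1.1762	-0.6288	-1.919	-0.7559
ATA	-0.1436	-0.6904	-0.9298	-0.0146	-0.5605	-0.7223	-2.1735	-0.3435	-1.0211	0.6372	0.2185	0.4596
ATC	0.9383	0.4587	-0.3396	-0.073	-0.0203	-2.7197	-0.7629	-0.3743	0.1701	0.0908	0.0978	-0.7732
ATG	0.639	-0.4085	0.7457	0.0285	1.5287	0.3359	1.5623	1.8197	-0.3256	-0.837	-0.5491	-0.0088
ATT	0.167	-1.5067	-1.8479	1.8703	2.1908	-0.0137	-0.2712	0.2951	0.3577	-2.0677	0.9548	-2.4825
CAA	0.5957	-0.3881	0.9543	0.1554	-0.7009	1.179	0.1674	-1.561	0.2123	0.8822	2.6669	-1.5732
CAC	0.7992	0.1038	-1.675	0.0975	-2.2082	-1.2533	0.4273	1.0118	2.35	1.0222	-0.1027	0.7
CAG	-0.6745	-0.4228	-0.4395	-1.1345	-0.3763	-0.3661	-0.8935	1.382	-1.6598	0.2372	-0.824	-0.2764
CAT	0.803	0.0149	0.5019	-0.1169	0.1878	1.3144	-1.222	0.7809	0.8613	2.3122	1.5037	2.0344
CCA	0.6115	0.1845	0.3571	0.0262	0.0514	0.536	-0.1821	0.4472	-0.7775	0.1729	1.1012	-0.6815
CCC	1.3808	-0.5912	-0.8107	0.2204	-1.2171	1.4054	1.0281	-0.0576	1.9294	1.5359	-0.3792	0.3661
CCG	-0.3115	0.7361	-1.2241	-0.8096	-0.3656	0.8387	0.9455	-0.6674	-0.0179	-0.5954	-1.0221	1.0569
CCT	-1.2078	-2.1481	-1.7952	0.7155	-2.0935	-1.315	0.8529	0.616	-1.1028	-2.0163	0.6984	0.8205
CGA	-0.181	1.6784	1.5468	0.9664	-0.5746	0.9489	-0.595	0.8274	1.976	-2.0082	0.6674	-2.0651
CGC	0.7607	-0.0344	2.0006	-0.0167	0.5189	-0.3189	-0.0409	0.4774	0.2136	-0.4138	-0.8221	0.0144
CGG	0.0297	0.3225	0.7214	-0.4167	0.7194	0.3503	-0.9204	-1.0848	-0.9482	-0.1744	0.1611	0.3946
CGT	-0.0177	-0.878	0.2493	0.7673	0.0733	-1.0519	0.7648	-0.5506	2.0956	-0.9108	0.5335	-0.1293
CTA	-1.4636	2.0904	0.3598	-0.0628	-0.1854	1.274	0.7041	0.2197	1.2078	0.6023	-1.7621	0.579
CTC	0.3672	-0.4985	0.789	-0.0698	-0.1885	-0.3599	0.8525	0.4405	0.7603	0.9645	-1.1303	0.1581
CTG	-0.3227	2.5392	-0.4157	1.3918	0.7672	-0.2488	-0.6613	0.2383	0.1005	-0.2974	0.5308	-0.4846
CTT	0.0845	1.2969	-0.9308	-0.3419	0.5604	-0.6253	-1.1962	0.9436	-0.5178	0.6111	0.6303	-0.9534
GAA	-1.1209	0.3803	0.3653	1.115	1.3881	-1.3229	0.5016	1.0174	0.9238	-0.9104	-0.5119	-0.469
GAC	0.1539	-1.7374	1.4545	1.025	-1.0146	-2.1138	0.9661	-1.8966	1.0495	0.7541	0.7767	0.9021
GAG	0.729	-0.6678	0.6884	0.5288	0.161	0.0331	-1.7407	-1.003	-1.3433	-2.0476	0.7412	-1.4927
GAT	1.2776	0.5456	1.0399	-0.1193	1.6011	0.1491	0.6839	0.5119	-0.3536	-1.3961	0.1857	1.0682
GCA	1.0916	0.7389	0.0872	-0.0385	-1.9811	0.2617	0.8028	-0.9763	-0.2856	-0.3645	0.2963	-0.4884
GCC	0.2262	-0.5076	-0.9407	-1.6211	-0.7783	1.162	-0.151	0.9056	-0.8068	-0.3119	-0.8256	-0.1154
GCG	0.9831	-0.0782	0.5992	0.1637	1.5312	-1.033	-1.1389	-1.3523	-0.179	0.2045	0.8573	0.2667
GCT	-0.8559	-1.0089	-1.0855	-1.0121	-2.4136	0.3699	-1.7037	-1.0222	-0.3972	-1.0279	2.7306	1.4248
GGA	0.2925	0.3225	0.5887	-0.7221	0.3015	-0.6811	0.5455	-0.0592	-1.2871	1.3467	0.7895	-0.7007
GGC	2.3	0.6639	-0.8601	0.2254	-1.3507	0.5811	-1.0281	0.8479	0.8097	0.3044	-0.9008	2.5387
GGG	-0.8827	-0.778	0.5772	-0.6955	-0.0647	1.1322	0.2255	-1.6669	0.7221	-1.1919	0.3797	-0.4184
GGT	0.3828	-0.3356	1.5848	-1.5573	0.0327	0.0367	0.9389	0.4577	-1.0764	-1.6145	-0.98	-0.0609
GTA	-0.7038	0.8284	0.2282	-0.6564	0.6147	-1.2594	1.7327	-0.1375	1.16	1.9562	-1.1781	1.0959
GTC	-2.848	-2.178	-0.4713	0.5932	-0.9508	0.2291	-0.8135	1.1077	0.511	0.5925	0.6827	-0.6165
GTG	1.1106	0.2203	-0.8438	-1.5761	-0.1538	0.0794	0.9347	-0.1266	-0.9269	0.8529	1.2412	0.4474
GTT	1.326	0.3341	-0.911	0.0037	0.4307	-0.4238	-1.5187	-0.8235	-1.0032	-0.1672	-1.0812	-0.8918
TAA	-0.6834	0.0947	-0.7278	-1.6024	0.9709	1.3611	-1.5686	0.8794	-1.035	-0.1589	-0.9798	0.5052
TAC	0.312	-0.1944	-0.324	0.7958	-0.4898	0.8585	-2.0167	-0.1456	0.6509	0.7969	-0.4634	-0.3695
TAG	-1.9557	1.8877	0.7733	-0.5502	0.5856	-0.1327	-0.3907	1.328	1.0607	-0.4124	-0.7133	-0.1312
TAT	-0.4704	1.2623	-0.2849	0.8725	0.5237	0.9345	0.0669	-0.2771	-0.3702	1.1508	0.6851	-1.2901
TCA	-1.371	-0.4088	1.0778	0.5569	0.2777	-0.2948	0.2843	-1.2672	-1.5433	0.0081	-0.9866	-0.4719
TCC	-0.389	0.4192	-0.137	1.9261	0.119	0.021	0.7791	0.3521	-0.3563	0.8198	1.5905	0.9724
TCG	-0.4712	-0.1572	0.2863	1.2773	0.0958	-0.6391	0.3817	-0.8259	0.2876	2.0997	0.9926	0.0999
TCT	-0.6723	-0.4216	0.524	1.1061	-0.075	0.628	1.1728	1.4223	0.198	-1.2583	-0.0798	-1.1907
TGA	-0.5641	-1.0911	-2.4722	1.5516	-0.0761	1.255	0.661	-1.0669	-0.7956	0.2466	0.7894	-0.359
TGC	-0.8408	0.978	0.9387	-1.5594	2.418	-0.9251	1.0039	0.4087	-0.6201	-0.6848	-0.6603	1.3609
TGG	0.4794	-0.5078	0.5353	1.9493	-0.34	1.9289	0.3618	0.4876	-0.2992	-0.5147	-0.413	0.991
TGT	0.4981	-1.4823	0.0357	0.7619	0.9986	-1.1627	-0.7446	-2.9675	-0.1357	-0.803	0.1772	-0.0162
TTA	1.1926	-0.5191	-0.7773	-0.9555	1.8985	0.6073	-0.2155	1.8544	-0.2209	0.0192	-0.9526	0.4895
TTC	-0.6148	0.2037	1.8087	-2.2882	0.12	-2.0795	-1.448	-1.7271	0.5978	0.4092	0.5432	0.3664
TTG	0.1477	2.0609	0.8223	1.814	-0.8983	-0.1584	1.0566	0.4698	1.6151	0.2702	-0.2257	1.5658
TTT	-0.291	0.3661	0.6293	0.4658	0.0475	0.7876	1.641	-0.9684	1.0438	0.3385	-0.624	0.4087
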