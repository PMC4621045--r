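marker_id	chrom	pos	counted_allele	other_allele	freq_AFR	freq_EUR	freq_NAM	is_indel	source_tag
rs8916308	chr1	1693550	A	G	0.7863	0.6508	0.2145	FALSE	synthetic
rs0606097	chr1	3737424	A	T	0.7281	0.8436	0.2158	FALSE	synthetic
rs7862551	chr1	6129776	A	T	0.9331	0.2853	0.117	FALSE	synthetic
rs7709203	chr1	7303348	C	G	0.2126	0.9132	0.864	FALSE	synthetic
rs0334701	chr1	9476795	A	G	0.3461	0.1445	0.9698	FALSE	synthetic
rs6044839	chr2	2181657	T	A	0.8051	0.1131	0.4545	FALSE	synthetic
rs1946079	chr2	3352844	T	A	0.2001	0.9497	0.8933	FALSE	synthetic
rs7998643	chr2	4208275	A	C	0.7268	0.0823	0.461	FALSE	synthetic
rs3393673	chr2	6536826	T	C	0.1952	0.706	0.4675	FALSE	synthetic
rs9968126	chr2	8796009	A	T	0.7815	0.1134	0.9284	FALSE	synthetic
rs7258613	chr2	10556221	G	A	0.7326	0.2993	0.2065	FALSE	synthetic
rs6677260	chr2	13145476	G	A	0.8577	0.1489	0.6766	FALSE	synthetic
rs0471142	chr2	13777558	T	G	0.2758	0.6702	0.7773	FALSE	synthetic
rs7085973	chr3	2489184	T	C	0.0887	0.1171	0.8124	FALSE	synthetic
rs7222908	chr3	3666316	G	C	0.7454	0.0354	0.7811	FALSE	synthetic
rs4054438	chr3	5478711	A	G	0.7397	0.2376	0.0544	FALSE	synthetic
rs5865300	chr4	3346486	T	G	0.6181	0.1963	0.8511	FALSE	synthetic
rs4248875	chr4	5067758	C	G	0.8881	0.0286	0.0919	FALSE	synthetic
rs7827979	chr4	7163467	C	A	0.2212	0.7108	0.3764	FALSE	synthetic
rs9608822	chr4	9381331	A	G	0.7273	0.7404	0.1194	FALSE	synthetic
rs6372514	chr4	11819210	A	C	0.7057	0.5837	0.2968	FALSE	synthetic
rs1650698	chr4	14152878	A	G	0.923	0.2362	0.1742	FALSE	synthetic
rs1891776	chr5	1887526	C	G	0.7723	0.2981	0.2876	FALSE	synthetic
rs7826136	chr5	4346983	A	C	0.1053	0.783	0.2245	FALSE	synthetic
rs3477028	chr5	6886517	G	C	0.0691	0.1925	0.8658	FALSE	synthetic
rs5735576	chr5	7654524	G	T	0.055	0.8717	0.2043	FALSE	synthetic
rs8741527	chr5	9032685	T	A	0.9409	0.891	0.1764	FALSE	synthetic
rs6280573	chr7	2817586	C	T	0.5528	0.1844	0.946	FALSE	synthetic
rs5067832	chr7	3501196	G	T	0.2938	0.9012	0.2686	FALSE	synthetic
rs8366771	chr7	5877683	C	A	0.7871	0.0873	0.5339	FALSE	synthetic
rs8341356	chr7	7298697	G	A	0.1376	0.7574	0.0692	FALSE	synthetic
rs8665310	chr7	8092596	A	T	0.0633	0.3997	0.7449	FALSE	synthetic
rs7131228	chr8	3433379	C	G	0.7242	0.4229	0.1521	FALSE	synthetic
rs9750672	chr8	5886944	C	T	0.5417	0.0764	0.9007	FALSE	synthetic
rs7031552	chr8	6604120	A	T	0.2215	0.8003	0.206	FALSE	synthetic
rs1244505	chr8	8685670	A	T	0.2045	0.6736	0.9257	FALSE	synthetic
rs9053477	chr8	11069717	C	G	0.9418	0.7509	0.2675	FALSE	synthetic
rs1456426	chr8	12120470	C	G	0.8861	0.2556	0.7775	FALSE	synthetic
rs0644138	chr9	2362247	T	G	0.2397	0.0554	0.7147	FALSE	synthetic
rs2047512	chr9	4938392	T	C	0.1008	0.8972	0.5102	FALSE	synthetic
rs4672479	chr9	6263059	T	G	0.1008	0.2064	0.9762	FALSE	synthetic
rs2398692	chr9	7290439	C	T	0.9471	0.2832	0.9713	FALSE	synthetic
rs4134270	chr10	3380378	T	A	0.2611	0.8908	0.1971	FALSE	synthetic
rs2830053	chr10	4721730	C	A	0.6913	0.2947	0.8047	FALSE	synthetic
rs4070289	chr10	5865982	G	T	0.1138	0.9552	0.0874	FALSE	synthetic
rs9721884	chr10	6860760	G	C	0.7141	0.0457	0.6335	FALSE	synthetic
rs7085974	chr10	8687457	G	A	0.2211	0.9455	0.206	FALSE	synthetic
rs5244123	chr10	10755618	G	T	0.8821	0.6838	0.0835	FALSE	synthetic
rs5891875	chr11	1635746	T	A	0.7908	0.5701	0.2425	FALSE	synthetic
rs3557061	chr12	3315959	G	T	0.1288	0.7238	0.9559	FALSE	synthetic
rs9726704	chr12	5559678	A	T	0.0931	0.9164	0.095	FALSE	synthetic
rs3095024	chr12	7644822	A	G	0.8668	0.7362	0.1711	FALSE	synthetic
rs9679277	chr13	1715271	T	G	0.1084	0.9432	0.3636	FALSE	synthetic
rs5770247	chr13	3464494	G	A	0.1374	0.8279	0.3493	FALSE	synthetic
rs2133879	chr13	4692916	A	G	0.4006	0.8355	0.1055	FALSE	synthetic
rs8785067	chr14	2163782	C	T	0.2985	0.9092	0.1857	FALSE	synthetic
rs8525774	chr14	2941761	T	G	0.6009	0.0872	0.8744	FALSE	synthetic
rs3328877	chr14	4315199	A	T	0.7717	0.1867	0.8134	FALSE	synthetic
rs2436444	chr15	2079613	A	G	0.4144	0.1213	0.8701	FALSE	synthetic
rs6328930	chr15	3026978	A	T	0.1747	0.3828	0.9402	FALSE	synthetic
rs9617567	chr16	3139673	C	T	0.2479	0.4905	0.7568	FALSE	synthetic
rs7393331	chr16	4006112	T	A	0.8933	0.2008	0.2685	FALSE	synthetic
rs8152574	chr16	4785036	T	G	0.8219	0.8067	0.1723	FALSE	synthetic
rs2533190	chr17	3154334	T	C	0.112	0.8238	0.8387	FALSE	synthetic
rs7142567	chr17	4770414	G	A	0.6188	0.9053	0.1035	FALSE	synthetic
rs2564197	chr17	6028340	A	G	0.2838	0.5766	0.7395	FALSE	synthetic
rs8838978	chr17	7713314	T	G	0.7391	0.911	0.0412	FALSE	synthetic
rs8533814	chr17	9346005	G	T	0.9492	0.0911	0.8211	FALSE	synthetic
rs7383187	chr18	3166604	T	A	0.8945	0.0632	0.758	FALSE	synthetic
rs3749452	chr18	4803789	A	C	0.2977	0.8051	0.7377	FALSE	synthetic
rs3267179	chr19	1636456	A	G	0.0506	0.2453	0.8236	FALSE	synthetic
rs3500178	chr19	3834115	G	C	0.9665	0.0811	0.8983	FALSE	synthetic
rs1724012	chr19	5012657	G	T	0.1683	0.9205	0.8115	FALSE	synthetic
rs1086531	chr19	5944301	A	T	0.0621	0.0662	0.9682	FALSE	synthetic
rs5866195	chr19	8442627	A	T	0.3451	0.7822	0.1408	FALSE	synthetic
rs1331166	chr20	3069541	T	A	0.1543	0.2641	0.848	FALSE	synthetic
rs1502628	chr20	4554701	G	T	0.3719	0.2842	0.9405	FALSE	synthetic
rs9897428	chr21	2726276	A	C	0.3015	0.9154	0.1945	FALSE	synthetic
rs2586064	chr21	5053894	G	C	0.102	0.7707	0.6971	FALSE	synthetic
rs4918257	chr21	6819494	A	T	0.8416	0.2587	0.1155	FALSE	synthetic
rs8749638	chr22	3337446	T	A	0.0577	0.1574	0.9269	FALSE	synthetic
rs3605951	chr22	5818743	C	T	0.285	0.7733	0.0982	FALSE	synthetic
rs0946749	chr22	8053559	C	G	0.044	0.8933	0.7097	FALSE	synthetic
rs6671104	chr22	9761480	A	G	0.8135	0.2135	0.8296	FALSE	synthetic
rs2722167	chr22	10925392	G	T	0.7404	0.2488	0.8329	FALSE	synthetic
rs6023213	chr22	12968860	C	T	0.0878	0.8685	0.7064	FALSE	synthetic
rs4043133	chr22	14296611	G	A	0.723	0.5798	0.1506	FALSE	synthetic
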