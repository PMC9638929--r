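# synthetic example count table (60 genes)
# generated by polyprof::make_count_table(fixture_spec(seed = 101, n_genes = 60, depth_fp = 2e5, depth_rna = 2e5))
gene_id	length_nt	fp_count	rna_count
g0001	1295	1007	1300
g0002	1923	308	569
g0003	1107	317	759
g0004	1652	1624	2431
g0005	1725	3901	3495
g0006	2544	1780	4929
g0007	1982	630	1314
g0008	1426	1861	2136
g0009	2266	4993	2860
g0010	1357	775	1663
g0011	1901	5610	11330
g0012	1049	11652	6948
g0013	2852	5809	11943
g0014	775	655	1004
g0015	1348	583	288
g0016	1375	217	699
g0017	1023	7770	1850
g0018	1540	1738	594
g0019	1038	5457	1602
g0020	596	1420	752
g0021	1393	7218	11743
g0022	2063	4781	8139
g0023	1330	528	1052
g0024	776	1278	588
g0025	2097	547	487
g0026	795	2622	1733
g0027	1851	2657	2398
g0028	1422	5744	7219
g0029	1851	3450	4911
g0030	1877	7160	11553
g0031	2244	5060	10952
g0032	1701	2241	2238
g0033	2361	862	2152
g0034	590	1518	397
g0035	2562	2083	4412
g0036	1083	172	638
g0037	1618	1623	1346
g0038	2270	27322	11742
g0039	707	2762	1554
g0040	1835	1019	1080
g0041	1864	2664	3315
g0042	2110	1401	1512
g0043	528	6747	5965
g0044	1220	2440	5240
g0045	912	2312	2603
g0046	1798	2454	1891
g0047	1938	1367	2717
g0048	1092	106	156
g0049	1316	1248	1117
g0050	769	3462	5443
g0051	894	1464	680
g0052	1326	1467	1708
g0053	1946	2660	2245
g0054	800	17161	5312
g0055	2101	5229	5936
g0056	935	1961	529
g0057	1616	1032	1133
g0058	2494	848	1453
g0059	2544	2241	1852
g0060	1237	2982	4393
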