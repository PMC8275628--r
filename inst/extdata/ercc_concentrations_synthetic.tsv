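ercc_id	concentration	length
ERCC-00001	1	250
ERCC-00002	1	269
ERCC-00003	1	288
ERCC-00004	1	308
ERCC-00005	2	327
ERCC-00006	2	346
ERCC-00007	2	365
ERCC-00008	2	385
ERCC-00009	4	404
ERCC-00010	4	423
ERCC-00011	4	442
ERCC-00012	4	462
ERCC-00013	8	481
ERCC-00014	8	500
ERCC-00015	8	519
ERCC-00016	8	538
ERCC-00017	16	558
ERCC-00018	16	577
ERCC-00019	16	596
ERCC-00020	16	615
ERCC-00021	32	635
ERCC-00022	32	654
ERCC-00023	32	673
ERCC-00024	32	692
ERCC-00025	64	712
ERCC-00026	64	731
ERCC-00027	64	750
ERCC-00028	64	769
ERCC-00029	128	788
ERCC-00030	128	808
ERCC-00031	128	827
ERCC-00032	128	846
ERCC-00033	256	865
ERCC-00034	256	885
ERCC-00035	256	904
ERCC-00036	256	923
ERCC-00037	512	942
ERCC-00038	512	962
ERCC-00039	512	981
ERCC-00040	512	1000
ERCC-00041	1024	1019
ERCC-00042	1024	1038
ERCC-00043	1024	1058
ERCC-00044	1024	1077
ERCC-00045	2048	1096
ERCC-00046	2048	1115
ERCC-00047	2048	1135
ERCC-00048	2048	1154
ERCC-00049	4096	1173
ERCC-00050	4096	1192
ERCC-00051	4096	1212
ERCC-00052	4096	1231
ERCC-00053	8192	1250
ERCC-00054	8192	1269
ERCC-00055	8192	1288
ERCC-00056	8192	1308
ERCC-00057	16384	1327
ERCC-00058	16384	1346
ERCC-00059	16384	1365
ERCC-00060	16384	1385
ERCC-00061	32768	1404
ERCC-00062	32768	1423
ERCC-00063	32768	1442
ERCC-00064	32768	1462
ERCC-00065	65536	1481
ERCC-00066	65536	1500
ERCC-00067	65536	1519
ERCC-00068	65536	1538
ERCC-00069	131072	1558
ERCC-00070	131072	1577
ERCC-00071	131072	1596
ERCC-00072	131072	1615
ERCC-00073	262144	1635
ERCC-00074	262144	1654
ERCC-00075	262144	1673
ERCC-00076	262144	1692
ERCC-00077	524288	1712
ERCC-00078	524288	1731
ERCC-00079	524288	1750
ERCC-00080	524288	1769
ERCC-00081	1048576	1788
ERCC-00082	1048576	1808
ERCC-00083	1048576	1827
ERCC-00084	1048576	1846
ERCC-00085	2097152	1865
ERCC-00086	2097152	1885
ERCC-00087	2097152	1904
ERCC-00088	2097152	1923
ERCC-00089	4194304	1942
ERCC-00090	4194304	1962
ERCC-00091	4194304	1981
ERCC-00092	4194304	2000
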