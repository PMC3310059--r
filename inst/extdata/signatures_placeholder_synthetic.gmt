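Lequerre_20	synthetic placeholder symbols	GENE000001	GENE000002	GENE000003	GENE000004	GENE000005	GENE000006	GENE000007	GENE000008	GENE000009	GENE000010	GENE000011	GENE000012	GENE000013	GENE000014	GENE000015	GENE000016	GENE000017	GENE000018	GENE000019	GENE000020
Stuhlmuller_11	synthetic placeholder symbols	GENE000021	GENE000022	GENE000023	GENE000024	GENE000025	GENE000026	GENE000027	GENE000028	GENE000029	GENE000030	GENE000031
Stuhlmuller_82	synthetic placeholder symbols	GENE000032	GENE000033	GENE000034	GENE000035	GENE000036	GENE000037	GENE000038	GENE000039	GENE000040	GENE000041	GENE000042	GENE000043	GENE000044	GENE000045	GENE000046	GENE000047	GENE000048	GENE000049	GENE000050	GENE000051	GENE000052	GENE000053	GENE000054	GENE000055	GENE000056	GENE000057	GENE000058	GENE000059	GENE000060	GENE000061	GENE000062	GENE000063	GENE000064	GENE000065	GENE000066	GENE000067	GENE000068	GENE000069	GENE000070	GENE000071	GENE000072	GENE000073	GENE000074	GENE000075	GENE000076	GENE000077	GENE000078	GENE000079	GENE000080	GENE000081	GENE000082	GENE000083	GENE000084	GENE000085	GENE000086	GENE000087	GENE000088	GENE000089	GENE000090	GENE000091	GENE000092	GENE000093	GENE000094	GENE000095	GENE000096	GENE000097	GENE000098	GENE000099	GENE000100	GENE000101	GENE000102	GENE000103	GENE000104	GENE000105	GENE000106	GENE000107	GENE000108	GENE000109	GENE000110	GENE000111	GENE000112	GENE000113
Lequerre_8	synthetic placeholder symbols	GENE000114	GENE000115	GENE000116	GENE000117	GENE000118	GENE000119	GENE000120	GENE000121
Sekiguchi_18	synthetic placeholder symbols	GENE000122	GENE000123	GENE000124	GENE000125	GENE000126	GENE000127	GENE000128	GENE000129	GENE000130	GENE000131	GENE000132	GENE000133	GENE000134	GENE000135	GENE000136	GENE000137	GENE000138	GENE000139
Julia_8	synthetic placeholder symbols	GENE000140	GENE000141	GENE000142	GENE000143	GENE000144	GENE000145	GENE000146	GENE000147
Stuhlmuller_3	synthetic placeholder symbols	GENE000148	GENE000149	GENE000150
Tanio_8	synthetic placeholder symbols	GENE000151	GENE000152	GENE000153	GENE000154	GENE000155	GENE000156	GENE000157	GENE000158
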