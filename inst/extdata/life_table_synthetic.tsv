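age	qx	qx_female	qx_male
35	0.001139232665757	0.00108709737854629	0.00173878846868025
36	0.00119380803215603	0.00113917735913194	0.00182206077193303
37	0.00125322169282059	0.00119587463553494	0.00191271285160555
38	0.00131790224387811	0.00125759826881378	0.00201139795711791
39	0.0013883161861446	0.0013247935048124	0.00211882702146482
40	0.0014649712658684	0.00139794496475909	0.00223577372862549
41	0.00154842010777665	0.00147758011529864	0.00236308002127383
42	0.00163926416560094	0.00156427304207563	0.002501662086142
43	0.00173815801735523	0.00165864855300468	0.00265251685738654
44	0.00184581403489406	0.00176138663953584	0.00281672908151354
45	0.00196300745970195	0.00187322732655926	0.00299547899084296
46	0.00209058191946857	0.00199497594410625	0.00319005063613531
47	0.00222945542279978	0.00212750885670598	0.00340184093287843
48	0.00238062687239743	0.00227177968914194	0.00363236947983558
49	0.00254518314024378	0.00242882609045747	0.00388328921278636
50	0.00272430675172789	0.00259977708136006	0.00415639796095801
51	0.00291928422928533	0.00278586103370881	0.00445365097841532
52	0.00313151514996702	0.00298841433451502	0.00477717452766502
53	0.00336252197543664	0.0032088907908755	0.00512928059788975
54	0.00361396071719197	0.00344887183646581	0.00551248284554284
55	0.00388763250432917	0.00371007760466557	0.00592951385046059
56	0.0041854961258975	0.00399437893805166	0.00638334378612471
57	0.00450968162481822	0.00430381040887429	0.00687720060817343
58	0.00486250502543475	0.00464058443020166	0.00741459187061533
59	0.00524648428199155	0.00500710654265757	0.00799932828433236
60	0.00566435654066864	0.00540599196705427	0.00863554913723397
61	0.00611909681315734	0.00584008351867904	0.00932774969965777
62	0.00661393816508524	0.00631247098447618	0.0100808107420894
63	0.00715239352779109	0.00682651206979512	0.0109000302947447
64	0.00773827924688579	0.00738585502664246	0.0117911577796841
65	0.00837574048557673	0.00799446308036189	0.0127604306455474
66	0.00906927860469366	0.00865664077621142	0.0138146136322395
67	0.00982378064451111	0.00937706237121583	0.0149610407874069
68	0.0106445510355512	0.0101608023997125	0.0162076603476964
69	0.0115373456662406	0.0110133685428908	0.0175630825847635
70	0.0125084084341954	0.0119407369330002	0.0190366306979393
71	0.0135645104045507	0.0129493900213592	0.0206383948112525
72	0.0147129916925719	0.0140463571353246	0.022379289100915
73	0.0159618061781242	0.0152392578424007	0.0242711120389451
74	0.0173195691456421	0.0165363482289479	0.0263266096876251
75	0.0187956079241136	0.0179465701856862	0.0285595419160277
76	0.020400015576185	0.0194796037713624	0.0309847513316457
77	0.0221437076525322	0.0211459226984321	0.0336182346246837
78	0.0240384819856719	0.0229568529490431	0.0364772159069021
79	0.02609708144469	0.0249246344844185	0.0395802214878124
80	0.0283332595069912	0.0270624859541327	0.042947155364864
81	0.0307618484228866	0.029384672241655	0.0465993745070501
82	0.033398829651089	0.0319065745965116	0.0505597627787294
83	0.0362614061251166	0.0346447629988001	0.0548528020777553
84	0.0393680757689875	0.0376170702754818	0.0595046389443038
85	0.0427387055118921	0.0408426673364846	0.0645431445290794
86	0.0463946048518242	0.0443421387183408	0.0699979653868839
87	0.0503585977832671	0.0481375574097077	0.0759005620791996
88	0.0546550916294584	0.05225255768215	0.0822842320235059
89	0.0593101410009002	0.0567124043562249	0.0891841124146663
90	0.0643515047339327	0.0615440565921989	0.0966371583638715
91	0.0698086932418888	0.0667762239016315	0.104682090654847
92	0.0757130032325036	0.0724394116257169	0.113359306710551
93	0.0820975362056782	0.0785659526142979	0.122710747506552
94	0.0889971965434834	0.0851900212623566	0.132779712276441
95	0.0964486643395471	0.0923476254164517	0.143610611955145
96	0.104490337390652	0.100076570952098	0.155248651434028
97	0.113162235996305	0.108416393047594	0.167739429906477
98	0.12250586339427	0.11740824734766	0.181128447930295
99	0.132564013820438	0.127094753334473	0.195460509409035
100	0.143380519347362	0.137519781324809	0.210779006606722
101	0.154999925865788	0.148728173619895	0.227125076693566
102	0.167467087879044	0.160765389491425	0.244536619336672
103	0.180826671249014	0.173677062949647	0.263047166691744
104	0.195122552750905	0.187508461682275	0.282684600040153
105	0.210397105370006	0.202303835272071	0.303469711496262
106	0.226690358838663	0.218105640916407	0.325414614944604
107	0.244039026122424	0.234953635531404	0.348521017919154
108	0.262475388602567	0.252883824502812	0.372778375749758
109	0.282026035772472	0.27192725965165	0.398161961161922
110	1	1	1
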