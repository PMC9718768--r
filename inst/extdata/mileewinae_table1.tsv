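gene	strand	from_M_mira	to_M_mira	start_M_mira	stop_M_mira	ig_M_mira	from_M_lamellata	to_M_lamellata	start_M_lamellata	stop_M_lamellata	ig_M_lamellata	from_M_sharpa	to_M_sharpa	start_M_sharpa	stop_M_sharpa	ig_M_sharpa	from_M_amplimacula	to_M_amplimacula	start_M_amplimacula	stop_M_amplimacula	ig_M_amplimacula	from_P_sexmaculata	to_P_sexmaculata	start_P_sexmaculata	stop_P_sexmaculata	ig_P_sexmaculata
trnI	H	1	64				1	67				1	66				1	63				1	63			
trnQ	L	62	128			-3	65	131			-3	69	136			2	61	129			-3	61	128			-3
trnM	H	129	193				132	197				137	203				130	195				129	193			
nad2	H	194	1162	ATA	TAA		198	1166	ATA	TAA		204	1172	ATA	TAA		196	1161	ATA	TAA		194	1162	ATA	TAA	
trnW	H	1174	1245			11	1178	1246			11	1171	1231			-2	1160	1222			-2	1162	1224			-1
trnC	L	1238	1300			-8	1239	1300			-8	1224	1285			-8	1215	1276			-8	1217	1279			-8
trnY	L	1307	1370			6	1304	1366			3	1285	1348			-1	1286	1348			9	1289	1354			9
cox1	H	1379	2914	ATG	TAA	8	1374	2909	ATG	TAA	7	1347	2888	ATG	TAA	-2	1350	2885	ATG	TAG	1	1369	2904	ATG	TAA	14
trnL2	H	2916	2982			1	2911	2978			1	2884	2948			-5	2886	2951				2918	2984			13
cox2	H	2983	3659	ATG	TA		2979	3655	ATA	TA		2949	3629	ATA	TAA		2952	3631	ATG	TA		2985	3658	ATA	TA	
trnK	H	3660	3731				3656	3727				3630	3699				3632	3703				3659	3729			
trnD	H	3730	3792			-2	3726	3789			-2	3700	3761				3718	3780			14	3738	3803			8
atp8	H	3793	3945	TTG	TAA		3790	3942	TTG	TAA		3762	3914	TTG	TAA		3781	3933	TTG	TAA		3804	3956	TTG	TAA	
atp6	H	3939	4592	ATG	TAA	-7	3936	4589	ATG	TAA	-7	3908	4561	ATG	TAA	-7	3927	4580	ATG	TAA	-7	3950	4603	ATG	TAA	-7
cox3	H	4596	5375	ATG	TAA	3	4593	5372	ATG	TAA	3	4562	5341	ATG	TAA		4588	5367	ATG	TAA	7	4606	5385	ATG	TAA	2
trnG	H	5378	5440			2	5382	5447			9	5341	5403			-1	5367	5429			-1	5390	5451			4
nad3	H	5441	5794	ATT	TAG		5448	5801	ATA	TAA		5404	5754	ATC	TAG		5430	5783	ATT	TAA		5452	5805	ATT	TAG	
trnA	H	5793	5854			-2	5801	5862			-1	5753	5814			-2	5783	5845			-1	5804	5864			-2
trnR	H	5855	5919				5868	5929			5	5817	5879			2	5845	5911			-1	5864	5927			-1
trnN	H	5917	5980			-3	5927	5990			-3	5878	5944			-2	5909	5973			-3	5925	5990			-3
trnS1	H	5980	6046			-1	5990	6056			-1	5944	6010			-1	5973	6038			-1	5990	6055			-1
trnE	H	6046	6108			-1	6056	6119			-1	6010	6071			-1	6048	6112			9	6060	6123			4
trnF	L	6109	6171				6120	6184				6071	6132			-1	6113	6176				6125	6188			1
nad5	L	6171	7844	TTG	TAA	-1	6184	7857	TTG	TAA	-1	6132	7804	TTG	TA	-1	6176	7849	TTG	TAA	-1	6192	7865	TTG	TAA	3
trnH	L	7845	7910				7858	7920				7805	7868				7850	7915				7866	7930			
nad4	L	7911	9233	ATG	TAA		7921	9241	ATG	T		7868	9190	ATG	TAA	-1	7919	9235	ATG	TAA	3	7954	9273	ATA	TAA	23
nad4L	L	9227	9502	ATG	TAA	-7	9235	9510	ATG	TAA	-7	9184	9456	ATG	TAG	-7	9229	9504	ATT	TAA	-7	9273	9548	ATG	TAA	-1
trnT	H	9505	9571			2	9513	9579			2	9459	9525			2	9507	9573			2	9551	9614			2
trnP	L	9572	9635				9580	9643				9526	9586				9574	9639				9615	9678			
nad6	H	9638	10133	ATT	T	2	9646	10137	ATT	TAA	2	9589	10080	ATC	TAA	2	9642	10136	ATC	TAA	2	9681	10172	ATA	TAA	2
cytb	H	10122	11258	ATG	TAA	-12	10130	11266	ATG	TAA	-8	10073	11209	ATG	TAG	-8	10129	11265	ATG	TAA	-8	10165	11301	ATG	TAA	-8
trnS2	H	11257	11324			-2	11265	11332			-2	11208	11272			-2	11270	11334			4	11326	11392			24
nad1	L	11326	12253	ATT	T	1	11334	12261	ATT	T	1	11274	12204	ATA	T	1	11337	12264	ATT	T	2	11394	12321	ATA	T	1
trnL1	L	12254	12319				12262	12327				12205	12272				12265	12331				12322	12386			
rrnL	L	12320	13515				12328	13523				12273	13452				12332	13548				12387	13593			
trnV	L	13516	13578				13524	13586				13453	13518				13549	13617				13594	13658			
rrnS	L	13579	14326				13587	14341				13519	14258				13618	14374				13659	14408			
control_region	H	14327	14917				14342	14787				14259	14859				14375	15436				14409	15404			
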