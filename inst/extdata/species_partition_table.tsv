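family	species	lmr	go	rc	bin	n_no_coi	abgd_group
Dermophiidae	Geotrypetes seraphini	0	0	1	ACM4617	0	85
Arthroleptidae	Arthroleptis adelphus	0	0	1	ACM4198	0	2
Arthroleptidae	Arthroleptis adelphus	7	0	0	ACM4199	0	1
Arthroleptidae	Arthroleptis perreti	1	0	0	ACM4527	0	4
Arthroleptidae	Arthroleptis cf. poecilonotus	2	0	9	ACM4055	0	3
Arthroleptidae	Arthroleptis sylvaticus	2	0	10	ACM4448	0	5
Arthroleptidae	Arthroleptis taeniatus	5	0	0	ACM4581	0	8
Arthroleptidae	Arthroleptis sp. A	3	0	0	ACM4312	0	7
Arthroleptidae	Arthroleptis sp. B	0	0	3	ACM4462	0	6
Arthroleptidae	Astylosternus batesi	0	0	6	ACM4639	0	53
Arthroleptidae	Cardioglossa leucomystax	0	0	3	ACM4070	0	11
Arthroleptidae	Cardioglossa gracilis	0	0	1	ACM4413	0	9
Arthroleptidae	Cardioglossa gratiosa	0	0	1	ACM4021	0	10
Arthroleptidae	Leptopelis aubryi	8	5	3	ACM4513	1	12
Arthroleptidae	Leptopelis aubryioides	0	0	2	ACM4562	0	18
Arthroleptidae	Leptopelis boulengeri	0	0	1	ACM4141	0	15
Arthroleptidae	Leptopelis sp. A	0	0	2	ACM4288	0	16
Arthroleptidae	Leptopelis brevirostris	1	0	0	ACM4142	0	13
Arthroleptidae	Leptopelis brevirostris	0	0	1	ACM4258	0	14
Arthroleptidae	Leptopelis cf. macrotis	0	0	1	ACM4257	0	19
Arthroleptidae	Leptopelis ocellatus	0	0	2	ACM4119	0	17
Arthroleptidae	Scotobleps gabonicus	0	0	1	ACM3974	0	73
Bufonidae	Amietophrynus camerunensis	0	0	19	ACM4516	3	36
Bufonidae	Amietophrynus funereus	0	0	1	ACM4379	0	39
Bufonidae	Amietophrynus gracilipes	0	0	18	ACM4666	0	38
Bufonidae	Amietophrynus gutturalis	0	0	5	ABX1848	0	37
Bufonidae	Amietophrynus pusilla	0	0	32	ABX1889	8	42
Bufonidae	Amietophrynus regularis	1	5	12	ACM4600	0	41
Bufonidae	Amietophrynus tuberosus	0	0	5	ACM4608	0	40
Bufonidae	Nectophryne afra	2	0	0	ACM4101	0	35
Bufonidae	Nectophryne afra	1	0	0	ACM4102	0	35
Conrauidae	Conraua crassipes	0	0	3	ACM4265	0	78
Dicroglossidae	Hoplobatrachus occipitalis	2	4	9	ABX2327	0	79
Hemisotidae	Hemisus perreti	3	1	0	ACM4439	0	84
Hemisotidae	Hemisus guieensis	0	0	4	ACM4440	0	83
Hyperoliidae	Afrixalus dorsalis	0	7	0	ACM4276	0	32
Hyperoliidae	Afrixalus dorsalis	0	1	0	ACM4277	0	33
Hyperoliidae	Afrixalus fulvovittatus	0	0	10	ACM3990	0	31
Hyperoliidae	Afrixalus osorioi	0	0	1	ACM4091	0	30
Hyperoliidae	Afrixalus osorioi	0	0	1	ACM3992	0	29
Hyperoliidae	Cryptothylax greshoffii	0	0	6	ACM4279	0	34
Hyperoliidae	Hyperolius adspersus	15	9	0	ACM4236	0	20
Hyperoliidae	Hyperolius adspersus	0	0	1	ACM3931	0	20
Hyperoliidae	Hyperolius adspersus	0	1	0	ACM4235	0	20
Hyperoliidae	Hyperolius olivaceus	0	5	0	ACM4149	0	22
Hyperoliidae	Hyperolius olivaceus	0	0	5	ACM4150	0	22
Hyperoliidae	Hyperolius olivaceus	8	7	0	ACM4237	0	22
Hyperoliidae	Hyperolius dartevellei	0	0	4	ACM4221	0	21
Hyperoliidae	Hyperolius ocellatus	1	0	0	ACM4613	0	24
Hyperoliidae	Hyperolius pardalis	0	0	1	ACM4378	0	26
Hyperoliidae	Hyperolius phantasticus	5	7	0	ACM4699	0	25
Hyperoliidae	Hyperolius platyceps	0	1	0	ACM3935	0	23
Hyperoliidae	Hyperolius platyceps	4	0	0	ACM3936	0	23
Hyperoliidae	Hyperolius tuberculatus	3	10	0	ACM4028	0	27
Hyperoliidae	Phlyctimantis leonardi	0	3	0	ACM4536	0	28
Hyperoliidae	Phlyctimantis leonardi	0	7	1	ACY0609	0	28
Phrynobatrachidae	Phrynobatrachus africanus	0	0	2	ACM4519	0	59
Phrynobatrachidae	Phrynobatrachus africanus	1	0	0	ACM4520	0	57
Phrynobatrachidae	Phrynobatrachus africanus	0	0	1	ACM4521	0	58
Phrynobatrachidae	Phrynobatrachus africanus	0	0	1	ACM4518	0	60
Phrynobatrachidae	Phrynobatrachus auritus	40	0	0	ACM3966	0	54
Phrynobatrachidae	Phrynobatrachus auritus	0	0	4	ACM3967	0	54
Phrynobatrachidae	Phrynobatrachus auritus	0	0	1	ACM4483	0	55
Phrynobatrachidae	Phrynobatrachus batesii	0	0	1	ACM3923	0	61
Phrynobatrachidae	Phrynobatrachus cf. hylaios	0	0	7	ACM4501	0	66
Phrynobatrachidae	Phrynobatrachus horsti	0	0	1	ACM3921	0	63
Phrynobatrachidae	Phrynobatrachus ruthbeateae	0	0	1	ACM3922	0	62
Phrynobatrachidae	Phrynobatrachus sp. A	21	1	0	ACM4053	0	56
Phrynobatrachidae	Phrynobatrachus sp. B	0	0	2	ACM4606	0	65
Phrynobatrachidae	Phrynobatrachus sp. C	0	0	1	ACM4544	0	64
Pipidae	Hymenochirus curtipes	0	0	5	ACM4325	0	74
Pipidae	Hymenochirus sp.	0	0	1	ACM4340	0	75
Pipidae	Xenopus andrei	1	0	2	AAH9248	0	67
Pipidae	Xenopus pygmaeus	0	0	8	AAW7585	0	68
Pipidae	Xenopus boumbaensis	0	0	1	AAH7184	0	69
Pipidae	Xenopus epitropicalis	0	0	3	AAJ6803	0	70
Pipidae	Xenopus mellotropicalis	7	4	0	AAH0940	0	72
Pipidae	Xenopus mellotropicalis	0	0	7	AAH0942	0	71
Ptychadenidae	Ptychadena mascareniensis	0	0	7	ACH6774	0	77
Ptychadenidae	Ptychadena porosissima	16	2	0	ACM4178	3	43
Ptychadenidae	Ptychadena taenioscelis	6	0	3	ACM4023	2	76
Ptychadenidae	Ptychadena uzungwensis	0	0	1	ACM4112	0	44
Ptychadenidae	Ptychadena sp. A	4	0	0	ACM4315	0	46
Ptychadenidae	Ptychadena sp. B	0	0	5	ACM4111	0	47
Ptychadenidae	Ptychadena sp. C	3	1	0	ACM4022	0	45
Ptychadenidae	Ptychadena sp. C	0	4	0	ACM4572	0	45
Pyxicephalidae	Aubria masako	0	0	3	ACM3984	0	82
Ranidae	Amnirana albolabris	4	0	0	ACM3918	0	48
Ranidae	Amnirana albolabris	0	0	1	ACM4391	0	50
Ranidae	Amnirana albolabris	0	0	9	ACM4408	0	49
Ranidae	Amnirana cf. amnicola	0	0	3	ACM4594	0	51
Ranidae	Amnirana lepus	0	0	7	ACM4529	0	52
Rhacophoridae	Chiromantis rufescens	0	0	1	ACM4211	0	81
Rhacophoridae	Chiromantis rufescens	0	5	0	ACM4212	1	80
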