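S03_r000004	bact_029	85.47	250	0	0	1	1	1	1	1.29632026602394e-38	205.4	252
S03_r000005	bact_057	91.73	254	0	0	1	1	1	1	1.72620130358151e-12	186.7	303
S03_r000006	bact_149	93.89	231	0	0	1	1	1	1	4.87379890254398e-31	191.6	258
S03_r000007	bact_184	89.93	320	0	0	1	1	1	1	1.69256603202537e-37	112.5	398
S03_r000008	bact_066	92.64	142	0	0	1	1	1	1	1.6526224194085e-29	213.6	170
S03_r000009	bact_014	83.01	224	0	0	1	1	1	1	4.33000068216254e-28	475.5	245
S03_r000011	bact_180	90.23	222	0	0	1	1	1	1	5.50563058141322e-08	449.3	229
S03_r000012	bact_199	89.97	169	0	0	1	1	1	1	1.65523553235367e-26	335.1	188
S03_r000013	bact_179	94.97	242	0	0	1	1	1	1	3.53356355172073e-40	152.6	285
S03_r000014	bact_090	84	188	0	0	1	1	1	1	2.438587199887e-24	449.2	192
S03_r000015	bact_070	86.95	161	0	0	1	1	1	1	1.65368676935669e-07	103.1	162
S03_r000016	bact_079	89.13	185	0	0	1	1	1	1	1.15310970994635e-09	340.3	207
S03_r000017	bact_046	92.44	257	0	0	1	1	1	1	5.15368297706284e-32	277.1	257
S03_r000018	bact_071	89.26	345	0	0	1	1	1	1	1.66961443384375e-33	226.8	395
S03_r000019	bact_008	87.43	224	0	0	1	1	1	1	4.95874844892069e-37	449	263
S03_r000020	bact_059	88.19	303	0	0	1	1	1	1	2.82618800109467e-36	190.7	389
S03_r000021	bact_105	90.82	188	0	0	1	1	1	1	1.39122073418045e-14	444.6	210
S03_r000022	bact_148	93.1	220	0	0	1	1	1	1	3.75118670672308e-21	384.2	267
S03_r000023	bact_059	94.59	148	0	0	1	1	1	1	3.16664926710602e-25	164	188
S03_r000024	bact_108	83.1	188	0	0	1	1	1	1	3.89189583522991e-23	240.6	221
S03_r000025	bact_044	89.21	337	0	0	1	1	1	1	3.02923459127341e-31	419.4	396
S03_r000026	bact_053	94.13	166	0	0	1	1	1	1	2.5794708928722e-24	429.4	191
S03_r000027	bact_020	91.55	237	0	0	1	1	1	1	1.02805509165123e-25	366.5	298
S03_r000028	bact_067	95.54	265	0	0	1	1	1	1	2.67838597863732e-36	210	268
S03_r000029	bact_025	93.13	237	0	0	1	1	1	1	2.35954603526693e-31	463.1	250
S03_r000030	bact_042	83.69	246	0	0	1	1	1	1	2.80547837920929e-06	101.1	248
S03_r000031	bact_187	95.45	251	0	0	1	1	1	1	1.2138128598897e-22	211	261
S03_r000032	bact_104	96.04	299	0	0	1	1	1	1	9.48756703056363e-25	401.5	312
S03_r000033	bact_028	84.91	218	0	0	1	1	1	1	6.22966894174293e-20	286.2	235
S03_r000034	bact_136	87.94	140	0	0	1	1	1	1	3.39607251206488e-10	200.8	157
S03_r000036	bact_022	95.01	351	0	0	1	1	1	1	4.8571783326863e-08	434.4	396
S03_r000038	bact_016	84.21	291	0	0	1	1	1	1	1.22269076252251e-35	201	372
S03_r000039	bact_191	96.03	207	0	0	1	1	1	1	1.09700751877611e-25	275.8	226
S03_r000040	bact_070	83.32	179	0	0	1	1	1	1	9.69044081688218e-29	130.6	201
S03_b000001	bact_147	88.81	302	0	0	1	1	1	1	5.72214065032162e-30	346.7	315
S03_b000002	bact_038	84.73	326	0	0	1	1	1	1	6.55628052551786e-18	467.9	354
S03_b000003	bact_155	96.79	298	0	0	1	1	1	1	4.14648102953866e-27	209.1	321
S03_b000004	bact_021	97.16	174	0	0	1	1	1	1	1.10105671634674e-28	213.2	211
S03_b000005	bact_047	94.1	218	0	0	1	1	1	1	1.06776595874553e-34	382.1	277
S03_b000006	bact_029	92.77	201	0	0	1	1	1	1	2.40314751695873e-17	471.9	214
S03_b000007	bact_156	96.64	256	0	0	1	1	1	1	2.08156706752328e-21	361.5	284
S03_b000008	bact_102	91.52	164	0	0	1	1	1	1	2.25607536117454e-17	434.2	198
S03_b000009	bact_159	83.97	259	0	0	1	1	1	1	1.74960991899525e-17	235.7	301
S03_b000010	bact_060	83.26	305	0	0	1	1	1	1	1.10407548649489e-30	401.2	333
S03_b000011	bact_054	83.59	305	0	0	1	1	1	1	4.08457343502605e-36	366.3	351
S03_b000012	bact_003	94.91	132	0	0	1	1	1	1	1.82557629414554e-13	449.7	162
S03_b000013	bact_016	85.37	220	0	0	1	1	1	1	1.340295137905e-29	243	273
S03_b000014	bact_025	87.4	163	0	0	1	1	1	1	1.06897243680664e-31	148.3	189
S03_b000015	bact_164	91.27	200	0	0	1	1	1	1	1.50271880585808e-24	252.5	234
S03_b000016	bact_048	92.92	175	0	0	1	1	1	1	1.00923828793435e-29	424.8	188
S03_b000017	bact_040	86.29	160	0	0	1	1	1	1	3.9080225820915e-28	211.7	203
S03_b000018	bact_172	92.83	247	0	0	1	1	1	1	4.70255095032735e-31	290.7	251
S03_b000019	bact_171	86.83	186	0	0	1	1	1	1	2.43348271838001e-08	347.2	224
S03_b000020	bact_193	93.61	209	0	0	1	1	1	1	1.4001004692543e-19	360.6	246
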