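S04_r000001	bact_146	89.63	143	0	0	1	1	1	1	1.47115856104589e-18	289.2	177
S04_r000002	bact_022	89.42	136	0	0	1	1	1	1	5.00991180820857e-10	457.8	163
S04_r000003	bact_116	87.89	248	0	0	1	1	1	1	7.20512979465759e-10	414.4	262
S04_r000004	bact_065	86.42	167	0	0	1	1	1	1	5.47984478843095e-36	477.2	197
S04_r000005	bact_034	96.6	224	0	0	1	1	1	1	1.88800119486090e-11	355.8	263
S04_r000006	bact_162	88.17	148	0	0	1	1	1	1	7.98591129480043e-15	161.1	153
S04_r000007	bact_079	88.18	383	0	0	1	1	1	1	2.38122403503054e-38	299.7	385
S04_r000008	bact_195	96.26	130	0	0	1	1	1	1	9.95661572865555e-22	398.1	159
S04_r000010	bact_153	84.14	273	0	0	1	1	1	1	4.24080756584195e-06	335.3	293
S04_r000011	bact_040	85.97	270	0	0	1	1	1	1	4.55544805789721e-34	372.4	341
S04_r000012	bact_151	89.95	265	0	0	1	1	1	1	9.13696601517234e-29	435.5	304
S04_r000013	bact_164	84.3	176	0	0	1	1	1	1	2.71639086645299e-30	104.6	200
S04_r000014	bact_007	89.12	208	0	0	1	1	1	1	2.19980211589209e-11	285	260
S04_r000015	bact_092	85.5	200	0	0	1	1	1	1	6.30230607683445e-08	157.6	204
S04_r000016	bact_039	92.22	244	0	0	1	1	1	1	1.24905410598076e-21	410.4	260
S04_r000017	bact_142	96.53	316	0	0	1	1	1	1	2.88226377793091e-24	319.6	372
S04_r000018	bact_018	86.91	359	0	0	1	1	1	1	9.85251909434799e-37	405.9	389
S04_r000019	bact_123	83.19	199	0	0	1	1	1	1	3.66612104819939e-06	251.4	248
S04_r000020	bact_132	93.4	237	0	0	1	1	1	1	2.70442931325484e-15	289.2	244
S04_r000021	bact_190	91.43	280	0	0	1	1	1	1	2.48581872060894e-18	142.3	348
S04_r000022	bact_153	93.08	141	0	0	1	1	1	1	3.54655923141656e-28	447.9	174
S04_r000023	bact_129	90.2	321	0	0	1	1	1	1	3.45085566153188e-20	168.4	331
S04_r000024	bact_087	86.42	129	0	0	1	1	1	1	9.30936586747015e-32	305.2	162
S04_r000025	bact_152	95.95	297	0	0	1	1	1	1	4.38625612964177e-15	201.8	375
S04_r000026	bact_171	83.75	233	0	0	1	1	1	1	2.91651350531341e-22	132.2	257
S04_r000027	bact_025	82.32	262	0	0	1	1	1	1	5.72990344821494e-16	305.5	336
S04_r000028	bact_136	96.63	288	0	0	1	1	1	1	1.08230942436894e-22	380.3	356
S04_r000029	bact_157	88.18	138	0	0	1	1	1	1	4.91129576704179e-32	478.7	171
S04_r000030	bact_158	90.93	255	0	0	1	1	1	1	9.84865687700242e-23	317.4	280
S04_r000031	bact_176	93.13	241	0	0	1	1	1	1	1.55648738060459e-40	402.9	266
S04_r000032	bact_159	82.27	170	0	0	1	1	1	1	6.97281169310429e-16	155.8	188
S04_r000033	bact_110	90.09	199	0	0	1	1	1	1	9.44193757729122e-38	369.1	221
S04_r000034	bact_019	93.21	295	0	0	1	1	1	1	1.3278093813017e-35	467.8	339
S04_r000035	bact_041	89.78	357	0	0	1	1	1	1	2.30145210122887e-06	310.2	384
S04_r000036	bact_058	97.12	132	0	0	1	1	1	1	1.14905567141204e-40	182.5	151
S04_r000037	bact_008	96.61	332	0	0	1	1	1	1	2.42223236982039e-11	373.4	357
S04_r000038	bact_043	92.8	330	0	0	1	1	1	1	1.3719351790915e-38	355.5	364
S04_r000039	bact_015	86.78	208	0	0	1	1	1	1	2.71690373599811e-37	233.5	212
S04_r000040	bact_150	85.83	240	0	0	1	1	1	1	8.87057912002737e-26	487.3	265
S04_r000041	bact_093	92.11	255	0	0	1	1	1	1	1.2832674537974e-15	452.6	255
S04_b000001	bact_064	82.81	262	0	0	1	1	1	1	2.45218567381087e-12	392	296
S04_b000002	bact_057	91.03	266	0	0	1	1	1	1	9.41578494250134e-10	223	283
S04_b000003	bact_068	97.61	215	0	0	1	1	1	1	1.38225894270133e-16	111.6	275
S04_b000004	bact_174	95.48	329	0	0	1	1	1	1	6.56460153137304e-17	122.9	356
S04_b000005	bact_089	84.37	218	0	0	1	1	1	1	1.29533033569472e-09	434.8	270
S04_b000006	bact_135	83.5	146	0	0	1	1	1	1	1.17162012054355e-38	100.5	157
S04_b000007	bact_062	93.7	170	0	0	1	1	1	1	2.68597984254541e-19	447.6	187
S04_b000008	bact_086	89.12	302	0	0	1	1	1	1	2.37230225560976e-39	249.4	321
S04_b000009	bact_197	92.8	167	0	0	1	1	1	1	9.5281965331784e-17	186.5	195
S04_b000010	bact_158	91.11	287	0	0	1	1	1	1	5.51789087439765e-27	119.3	344
S04_b000011	bact_161	83.02	242	0	0	1	1	1	1	3.87192346800992e-26	201.9	309
S04_b000012	bact_124	89.19	295	0	0	1	1	1	1	1.39779149640248e-26	173	371
S04_b000013	bact_028	95.76	162	0	0	1	1	1	1	1.31836671125298e-11	266.2	188
S04_b000014	bact_069	97.46	180	0	0	1	1	1	1	2.09412955206752e-30	341.1	209
S04_b000015	bact_193	97.59	279	0	0	1	1	1	1	6.01619241842472e-17	159.2	300
S04_b000016	bact_097	87.94	235	0	0	1	1	1	1	1.76059707986403e-18	460.2	287
S04_b000017	bact_170	86.72	146	0	0	1	1	1	1	6.49747759609729e-21	261.1	173
S04_b000018	bact_057	84.29	184	0	0	1	1	1	1	3.72612496066705e-27	416.8	214
S04_b000019	bact_126	83.62	260	0	0	1	1	1	1	1.58149980453208e-07	480.6	281
S04_b000020	bact_189	91.89	266	0	0	1	1	1	1	1.52294140603759e-21	391.7	268
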