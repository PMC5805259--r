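S04_r000001	ref_s003	96.56	163	6	0	1	163	1	163	1.54524317877659e-21	283.3	177
S04_r000002	ref_s003	92.21	132	10	0	1	132	1	132	3.59499203391433e-26	219.1	163
S04_r000003	ref_s019	95.62	249	11	0	1	249	1	249	4.47367009959712e-32	428.6	262
S04_r000004	ref_s019	93.83	160	10	0	1	160	1	160	6.80384681621889e-30	270.2	197
S04_r000005	ref_s019	93.59	240	15	0	1	240	1	240	1.10015100316728e-29	404.3	263
S04_r000006	ref_s019	97	152	5	0	1	152	1	152	2.86638527147641e-24	265.4	153
S04_r000007	ref_s019	100	334	0	0	1	334	1	334	2.02800223781535e-34	601.2	385
S04_r000008	ref_s019	93.96	144	9	0	1	144	1	144	4.35937478949768e-13	243.5	159
S04_r000009	ref_s019	98.07	158	3	0	1	158	1	158	1.61662736980835e-25	278.9	169
S04_r000010	ref_s019	89.55	274	29	0	1	274	1	274	2.2527356512354e-07	441.6	293
S04_r000011	ref_s019	85.87	331	47	0	1	331	1	331	1.03154439729775e-35	511.6	341
S04_r000012	ref_s019	93.83	260	16	0	1	260	1	260	1.52166971563568e-24	439.1	304
S04_r000013	ref_s019	93.21	179	12	0	1	179	1	179	1.2341325945163e-35	300.3	200
S04_r000014	ref_s019	100	246	0	0	1	246	1	246	3.5610135310862e-11	442.8	260
S04_r000015	ref_s019	93.64	173	11	0	1	173	1	173	1.53188385746717e-29	291.6	204
S04_r000016	ref_s019	100	244	0	0	1	244	1	244	5.17261447020514e-13	439.2	260
S04_r000017	ref_s019	100	339	0	0	1	339	1	339	5.1316888653325e-14	610.2	372
S04_r000018	ref_s019	94.32	373	21	0	1	373	1	373	2.11643675865984e-37	633.3	389
S04_r000019	ref_s019	99.86	220	0	0	1	220	1	220	7.90740741382936e-27	395.5	248
S04_r000020	ref_s019	98.88	222	2	0	1	222	1	222	5.84611208012871e-35	395.1	244
S04_r000021	ref_s019	100	338	0	0	1	338	1	338	1.17222835383967e-21	608.4	348
S04_r000022	ref_s019	94.85	158	8	0	1	158	1	158	3.55216109146086e-06	269.8	174
S04_r000023	ref_s019	95.8	326	14	0	1	326	1	326	3.60598992661645e-25	562.2	331
S04_r000024	ref_s019	92.49	158	12	0	1	158	1	158	2.21293671323326e-22	263	162
S04_r000025	ref_s019	92.66	333	24	0	1	333	1	333	1.00484696245357e-20	555.4	375
S04_r000026	ref_s019	93.09	231	16	0	1	231	1	231	3.07980831214418e-33	387.1	257
S04_r000027	ref_s019	95.57	308	14	0	1	308	1	308	5.44282926107116e-09	529.9	336
S04_r000028	ref_s019	100	322	0	0	1	322	1	322	1.91375644304824e-16	579.6	356
S04_r000029	ref_s019	93.92	166	10	0	1	166	1	166	1.51931344400493e-30	280.6	171
S04_r000030	ref_s019	93.01	259	18	0	1	259	1	259	6.95682050570131e-28	433.6	280
S04_r000031	ref_s019	100	261	0	0	1	261	1	261	9.12168199215956e-30	469.8	266
S04_r000032	ref_s019	93.19	145	10	0	1	145	1	145	3.25926149797078e-35	243.2	188
S04_r000033	ref_s019	99.52	213	1	0	1	213	1	213	4.40708179115002e-29	381.6	221
S04_r000034	ref_s019	93.41	287	19	0	1	287	1	287	5.18524130069969e-27	482.5	339
S04_r000035	ref_s019	93.01	367	26	0	1	367	1	367	2.63175967172966e-24	614.4	384
S04_r000036	ref_s019	97.81	148	3	0	1	148	1	148	6.40679713380439e-37	260.6	151
S04_r000037	ref_s019	96.86	350	11	0	1	350	1	350	6.60953318459621e-24	610.2	357
S04_r000038	ref_s019	100	291	0	0	1	291	1	291	1.66857618101131e-39	523.8	364
S04_r000039	ref_s019	92.88	196	14	0	1	196	1	196	1.52135104183073e-14	327.7	212
S04_r000040	ref_s019	100	248	0	0	1	248	1	248	3.84988636567719e-31	446.4	265
S04_r000041	ref_s019	96.08	246	10	0	1	246	1	246	1.08778938805221e-37	425.4	255
S04_r000002	ref_s001	92.21	132	10	0	1	132	1	132	3.59499203391433e-26	219	163
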