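S03_r000001	ref_s001	100	324	0	0	1	324	1	324	9.5282408467778e-07	583.2	341
S03_r000002	ref_s006	93.96	238	14	0	1	238	1	238	6.36825426360494e-12	402.5	244
S03_r000003	ref_s006	97.32	168	5	0	1	168	1	168	2.15648095473231e-38	294.3	191
S03_r000004	ref_s015	88.8	225	25	0	1	225	1	225	2.43112755427521e-35	359.7	252
S03_r000005	ref_s015	99.95	260	0	0	1	260	1	260	4.17527154920619e-30	467.8	303
S03_r000006	ref_s015	85.33	239	35	0	1	239	1	239	5.76778260785263e-35	367.1	258
S03_r000007	ref_s015	100	379	0	0	1	379	1	379	7.53392629174874e-34	682.2	398
S03_r000008	ref_s015	92.72	154	11	0	1	154	1	154	1.23698782420824e-14	257	170
S03_r000009	ref_s015	94.37	205	12	0	1	205	1	205	2.31027292779435e-08	348.2	245
S03_r000010	ref_s015	94.57	233	13	0	1	233	1	233	4.22914909897947e-24	396.6	312
S03_r000011	ref_s015	97.55	186	5	0	1	186	1	186	7.93839331770614e-12	326.6	229
S03_r000012	ref_s015	88.66	185	21	0	1	185	1	185	1.01090324026195e-19	295.2	188
S03_r000013	ref_s015	97.74	230	5	0	1	230	1	230	2.1425905764364e-15	404.7	285
S03_r000014	ref_s015	100	188	0	0	1	188	1	188	2.23684517161653e-21	338.4	192
S03_r000015	ref_s015	95.82	150	6	0	1	150	1	150	3.68307356391937e-27	258.7	162
S03_r000016	ref_s015	96.42	188	7	0	1	188	1	188	2.7691816098922e-13	326.3	207
S03_r000017	ref_s015	95.47	254	12	0	1	254	1	254	8.00098476832173e-39	436.5	257
S03_r000018	ref_s015	93.7	357	22	0	1	357	1	357	1.73806480382105e-34	602.1	395
S03_r000019	ref_s015	88.59	236	27	0	1	236	1	236	4.43947735444479e-34	376.3	263
S03_r000020	ref_s015	97.27	370	10	0	1	370	1	370	1.06654733889621e-06	647.8	389
S03_r000021	ref_s015	100	193	0	0	1	193	1	193	1.3159302041591e-09	347.4	210
S03_r000022	ref_s015	100	215	0	0	1	215	1	215	1.57188287061974e-20	387	267
S03_r000023	ref_s015	95.1	150	7	0	1	150	1	150	8.21863566908884e-32	256.8	188
S03_r000024	ref_s015	93.04	202	14	0	1	202	1	202	1.00684845886346e-14	338.3	221
S03_r000025	ref_s015	91.56	325	27	0	1	325	1	325	1.68468014700427e-19	535.6	396
S03_r000026	ref_s015	90.48	183	17	0	1	183	1	183	1.28012379703069e-33	298	191
S03_r000027	ref_s015	85.99	239	33	0	1	239	1	239	2.14469463744411e-14	369.9	298
S03_r000028	ref_s015	95.41	240	11	0	1	240	1	240	2.69439872444299e-24	412.2	268
S03_r000029	ref_s015	95.8	239	10	0	1	239	1	239	2.83154468569246e-20	412.1	250
S03_r000030	ref_s015	100	223	0	0	1	223	1	223	2.56571832455711e-14	401.4	248
S03_r000031	ref_s015	96.76	221	7	0	1	221	1	221	6.38538722893963e-10	384.9	261
S03_r000032	ref_s015	96.51	289	10	0	1	289	1	289	5.1400342173149e-17	502	312
S03_r000033	ref_s015	95.72	216	9	0	1	216	1	216	8.41885986207852e-30	372.2	235
S03_r000034	ref_s015	95.27	138	7	0	1	138	1	138	5.03553497416093e-19	236.7	157
S03_r000035	ref_s015	97.47	305	8	0	1	305	1	305	3.03325574750626e-40	535.1	371
S03_r000036	ref_s015	96.4	361	13	0	1	361	1	361	1.83866552553274e-14	626.4	396
S03_r000037	ref_s015	92.27	318	25	0	1	318	1	318	7.65509366016825e-06	528.2	361
S03_r000038	ref_s015	98.86	310	4	0	1	310	1	310	3.94707241447096e-34	551.7	372
S03_r000039	ref_s015	93.97	223	13	0	1	223	1	223	2.20764103344249e-23	377.2	226
S03_r000040	ref_s015	97.64	196	5	0	1	196	1	196	3.57607643581799e-12	344.5	201
S03_r000038	ref_s013	98.86	310	4	0	1	310	1	310	3.94707241447096e-34	551.6	372
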