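S05_r000001	bact_096	88.59	251	0	0	1	1	1	1	2.89079131708767e-38	117.4	289
S05_r000002	bact_137	83.53	160	0	0	1	1	1	1	4.78298963047879e-18	456.6	190
S05_r000003	bact_038	92.04	334	0	0	1	1	1	1	5.74899714618998e-38	204.7	397
S05_r000004	bact_001	94.69	351	0	0	1	1	1	1	2.71498679576575e-14	418.4	352
S05_r000005	bact_123	88.58	150	0	0	1	1	1	1	2.19947578103063e-06	222.9	157
S05_r000006	bact_140	88.1	185	0	0	1	1	1	1	6.60490420486581e-39	383.9	203
S05_r000007	bact_151	86.87	352	0	0	1	1	1	1	2.76080708423601e-37	431.7	389
S05_r000008	bact_117	84.17	314	0	0	1	1	1	1	4.2996016384042e-23	254.1	352
S05_r000009	bact_122	96.96	203	0	0	1	1	1	1	3.06978584866948e-27	488.9	212
S05_r000010	bact_003	89.46	243	0	0	1	1	1	1	2.30743614536642e-19	254.7	302
S05_r000011	bact_112	82.03	253	0	0	1	1	1	1	8.58949531959365e-21	313.3	305
S05_r000012	bact_098	84.53	178	0	0	1	1	1	1	2.16382277722103e-17	388.1	225
S05_r000013	bact_010	82.25	313	0	0	1	1	1	1	9.47370585071637e-18	179.3	320
S05_b000001	bact_055	90.16	280	0	0	1	1	1	1	6.94354219415763e-26	178.2	283
S05_b000002	bact_110	84.86	313	0	0	1	1	1	1	1.53401234067871e-38	197.5	387
S05_b000003	bact_049	86.29	226	0	0	1	1	1	1	2.59202261804724e-17	208.5	272
S05_b000004	bact_046	84.6	268	0	0	1	1	1	1	1.07259808289796e-25	226	289
S05_b000005	bact_020	93.8	233	0	0	1	1	1	1	9.27154604894054e-36	382	284
S05_b000006	bact_117	87.15	324	0	0	1	1	1	1	2.68190781802402e-28	453	397
S05_b000007	bact_065	92.48	352	0	0	1	1	1	1	3.16939908039722e-20	217.9	363
S05_b000008	bact_044	90.51	226	0	0	1	1	1	1	1.40844940637748e-19	316.7	277
S05_b000009	bact_090	87.46	200	0	0	1	1	1	1	3.28648480862763e-08	216.8	222
S05_b000010	bact_079	93.17	288	0	0	1	1	1	1	7.41098084346735e-28	335.3	312
S05_b000011	bact_177	92.33	172	0	0	1	1	1	1	7.61158035388294e-25	400.8	182
S05_b000012	bact_106	92.05	135	0	0	1	1	1	1	4.02268770241222e-25	185.5	166
S05_b000013	bact_113	86.63	135	0	0	1	1	1	1	3.11569824434432e-27	472.4	169
S05_b000014	bact_080	97.13	184	0	0	1	1	1	1	9.48439280246299e-24	110.3	191
S05_b000015	bact_174	86.1	342	0	0	1	1	1	1	1.60979097506212e-30	229.1	369
S05_b000016	bact_003	89.2	138	0	0	1	1	1	1	1.18320064184324e-39	348.4	152
S05_b000017	bact_028	82.79	143	0	0	1	1	1	1	9.36938732380288e-24	287	175
S05_b000018	bact_181	92.3	197	0	0	1	1	1	1	5.03826364472555e-29	116.1	204
S05_b000019	bact_035	92.4	393	0	0	1	1	1	1	3.93716845181145e-30	241.6	398
S05_b000020	bact_011	89.87	222	0	0	1	1	1	1	3.64121323746917e-35	453.6	249
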