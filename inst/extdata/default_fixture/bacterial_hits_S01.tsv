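S01_r000001	bact_083	92.49	306	0	0	1	1	1	1	1.79021276724138e-31	350.8	306
S01_r000002	bact_034	93.02	157	0	0	1	1	1	1	5.18868755747949e-23	318.5	177
S01_r000003	bact_186	89.24	342	0	0	1	1	1	1	3.81273309472401e-37	171.7	397
S01_r000004	bact_038	92.21	344	0	0	1	1	1	1	9.27354660931029e-27	421.8	392
S01_r000006	bact_035	85.24	265	0	0	1	1	1	1	1.72116037032048e-39	303.5	270
S01_r000007	bact_186	86.03	260	0	0	1	1	1	1	5.60346387736091e-14	287.1	320
S01_r000008	bact_154	89.55	229	0	0	1	1	1	1	7.05281396779121e-36	408.5	252
S01_r000009	bact_189	89.65	154	0	0	1	1	1	1	5.81183856618216e-09	390.6	194
S01_r000010	bact_059	94.08	164	0	0	1	1	1	1	6.25665678737226e-38	121	183
S01_r000011	bact_010	95.96	320	0	0	1	1	1	1	3.75805510570769e-25	476.9	325
S01_r000012	bact_067	83.62	268	0	0	1	1	1	1	3.22879832752602e-12	418	294
S01_r000013	bact_003	85.24	364	0	0	1	1	1	1	1.07854354578345e-25	278.5	396
S01_r000014	bact_194	96.72	248	0	0	1	1	1	1	2.43068010588779e-14	290.9	298
S01_r000015	bact_091	83.49	236	0	0	1	1	1	1	2.26506869353954e-14	310.3	294
S01_b000001	bact_191	95.6	122	0	0	1	1	1	1	7.05269165024082e-16	223.9	150
S01_b000002	bact_154	83.66	125	0	0	1	1	1	1	2.97598964185412e-09	472.3	153
S01_b000003	bact_075	93.92	275	0	0	1	1	1	1	9.45237168796937e-17	437.8	310
S01_b000004	bact_094	93.29	318	0	0	1	1	1	1	1.23135585488408e-24	102.1	346
S01_b000005	bact_049	97.64	293	0	0	1	1	1	1	2.61317373131545e-31	196.5	356
S01_b000006	bact_005	83.34	167	0	0	1	1	1	1	1.79028953874681e-10	197.8	208
S01_b000007	bact_045	83.93	225	0	0	1	1	1	1	1.14644613682883e-08	397.8	245
S01_b000008	bact_106	82.09	239	0	0	1	1	1	1	2.09574840195141e-28	329.8	245
S01_b000009	bact_037	84.32	329	0	0	1	1	1	1	2.00058492997539e-11	364.6	378
S01_b000010	bact_018	92.94	156	0	0	1	1	1	1	1.665000048736e-20	277.7	196
S01_b000011	bact_064	91.49	330	0	0	1	1	1	1	9.60976589389853e-21	209.3	350
S01_b000012	bact_188	91.74	319	0	0	1	1	1	1	1.7087828121559e-09	415.8	350
S01_b000013	bact_060	93.59	350	0	0	1	1	1	1	8.22505806333475e-28	191	358
S01_b000014	bact_005	94.18	319	0	0	1	1	1	1	6.02534853413168e-32	481.5	372
S01_b000015	bact_043	91.56	144	0	0	1	1	1	1	5.44350449450665e-35	114.5	167
S01_b000016	bact_171	88.18	271	0	0	1	1	1	1	2.3746342386359e-27	157.2	308
S01_b000017	bact_113	91.62	137	0	0	1	1	1	1	6.47393196340734e-14	331.7	172
S01_b000018	bact_047	88.26	225	0	0	1	1	1	1	6.06717320990955e-19	302.3	259
S01_b000019	bact_113	88.44	223	0	0	1	1	1	1	1.43905809891421e-19	284.2	238
S01_b000020	bact_010	93.93	295	0	0	1	1	1	1	9.38332435123799e-30	171.4	327
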