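S01_r000001	ref_s011	90.76	291	27	0	1	291	1	291	3.31319857170024e-40	475.4	306
S01_r000002	ref_s011	93.31	171	11	0	1	171	1	171	6.69639749784768e-35	287.2	177
S01_r000003	ref_s011	89.38	394	42	0	1	394	1	394	1.99837131027777e-16	633.9	397
S01_r000004	ref_s011	96.25	369	14	0	1	369	1	369	1.61115420633476e-11	639.3	392
S01_r000005	ref_s014	92.01	316	25	0	1	316	1	316	1.24876118779265e-29	523.3	349
S01_r000006	ref_s014	100	262	0	0	1	262	1	262	4.47470854543817e-33	471.6	270
S01_r000007	ref_s014	91.45	299	26	0	1	299	1	299	2.14310265007185e-39	492.2	320
S01_r000008	ref_s014	92.34	229	18	0	1	229	1	229	1.75059430605666e-34	380.6	252
S01_r000009	ref_s014	97.82	166	4	0	1	166	1	166	1.30468560977143e-39	292.3	194
S01_r000010	ref_s014	91.22	182	16	0	1	182	1	182	1.65688884869005e-24	298.8	183
S01_r000011	ref_s015	96.73	286	9	0	1	286	1	286	2.52604648696016e-38	497.9	325
S01_r000012	ref_s015	98.04	274	5	0	1	274	1	274	8.84170408232451e-20	483.5	294
S01_r000013	ref_s015	94.59	269	15	0	1	269	1	269	2.07991908254148e-16	458	396
S01_r000014	ref_s015	95.26	271	13	0	1	271	1	271	2.75788609943799e-16	464.7	298
S01_r000015	ref_s015	97.16	269	8	0	1	269	1	269	7.78433321994071e-40	470.5	294
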