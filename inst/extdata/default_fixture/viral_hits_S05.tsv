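S05_r000001	ref_s001	96.22	260	10	0	1	260	1	260	1.48527739308347e-33	450.3	289
S05_r000002	ref_s015	93.39	155	10	0	1	155	1	155	1.95532624827141e-20	260.5	190
S05_r000003	ref_s015	95.1	371	18	0	1	371	1	371	1.75679715385093e-21	635.1	397
S05_r000004	ref_s015	98.37	328	5	0	1	328	1	328	3.99536175092692e-24	580.8	352
S05_r000005	ref_s015	91.85	138	11	0	1	138	1	138	1.26015634659622e-32	228.1	157
S05_r000006	ref_s015	100	162	0	0	1	162	1	162	3.73492581611637e-39	291.6	203
S05_r000007	ref_s015	96.5	333	12	0	1	333	1	333	8.27673070083643e-35	578.4	389
S05_r000008	ref_s015	91.86	336	27	0	1	336	1	336	9.39617387104889e-22	555.6	352
S05_r000009	ref_s015	97.48	201	5	0	1	201	1	201	2.61236376878612e-21	352.7	212
S05_r000010	ref_s015	91.42	247	21	0	1	247	1	247	1.49032305041611e-11	406.4	302
S05_r000011	ref_s021	93.25	283	19	0	1	283	1	283	9.53607242770804e-29	475	305
S05_r000012	ref_s021	94.49	189	10	0	1	189	1	189	6.9326192495141e-17	321.5	225
S05_r000013	ref_s021	96.8	279	9	0	1	279	1	279	1.71193129473632e-31	486.1	320
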