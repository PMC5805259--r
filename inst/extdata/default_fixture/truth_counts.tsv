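taxon_id	S01	S02	S03	S04	S05
s001	0	15	1	0	1
s002	0	12	0	0	0
s003	0	0	0	2	0
s004	0	2	0	0	0
s005	0	0	0	0	0
s006	0	13	2	0	0
s007	0	0	0	0	0
s008	0	0	0	0	0
s009	0	116	0	0	0
s010	0	0	0	0	0
s011	4	186	0	0	0
s012	0	0	0	0	0
s013	0	68	0	0	0
s014	6	0	0	0	0
s015	5	10	37	0	9
s016	0	0	0	0	0
s017	0	0	0	0	0
s018	0	0	0	0	0
s019	0	0	0	39	0
s020	0	0	0	0	0
s021	0	0	0	0	3
s022	0	0	0	0	0
s023	0	0	0	0	0
s024	0	0	0	0	0
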