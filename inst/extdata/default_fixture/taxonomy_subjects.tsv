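subject_id	taxon_id	viral_class
ref_s001	s001	bacteriophage
ref_s002	s002	bacteriophage
ref_s003	s003	bacteriophage
ref_s004	s004	eukaryotic_virus
ref_s005	s005	eukaryotic_virus
ref_s006	s006	eukaryotic_virus
ref_s007	s007	prophage
ref_s008	s008	prophage
ref_s009	s009	prophage
ref_s010	s010	prophage
ref_s011	s011	prophage
ref_s012	s012	prophage
ref_s013	s013	prophage
ref_s014	s014	prophage
ref_s015	s015	prophage
ref_s016	s016	bacteriophage
ref_s017	s017	bacteriophage
ref_s018	s018	bacteriophage
ref_s019	s019	prophage
ref_s020	s020	prophage
ref_s021	s021	prophage
ref_s022	s022	eukaryotic_virus
ref_s023	s023	eukaryotic_virus
ref_s024	s024	eukaryotic_virus
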