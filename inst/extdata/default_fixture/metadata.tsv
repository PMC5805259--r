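sample_id	sex
S01	F
S02	M
S03	F
S04	M
S05	M
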