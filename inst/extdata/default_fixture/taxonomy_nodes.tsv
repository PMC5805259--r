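taxon_id	name	rank	parent_id
o01	Order01	order	
o02	Order02	order	
o03	Order03	order	
f01	Family01	family	o01
f02	Family02	family	o02
f03	Family03	family	o03
f04	Family04	family	o01
f05	Family05	family	o02
f06	Family06	family	o03
f07	Family07	family	o01
f08	Family08	family	o02
s001	Virus_Family01_01	species	f01
s002	Virus_Family01_02	species	f01
s003	Virus_Family01_03	species	f01
s004	Virus_Family02_01	species	f02
s005	Virus_Family02_02	species	f02
s006	Virus_Family02_03	species	f02
s007	Virus_Family03_01	species	f03
s008	Virus_Family03_02	species	f03
s009	Virus_Family03_03	species	f03
s010	Virus_Family04_01	species	f04
s011	Virus_Family04_02	species	f04
s012	Virus_Family04_03	species	f04
s013	Virus_Family05_01	species	f05
s014	Virus_Family05_02	species	f05
s015	Virus_Family05_03	species	f05
s016	Virus_Family06_01	species	f06
s017	Virus_Family06_02	species	f06
s018	Virus_Family06_03	species	f06
s019	Virus_Family07_01	species	f07
s020	Virus_Family07_02	species	f07
s021	Virus_Family07_03	species	f07
s022	Virus_Family08_01	species	f08
s023	Virus_Family08_02	species	f08
s024	Virus_Family08_03	species	f08
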