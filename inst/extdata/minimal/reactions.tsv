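id	equation	lb	ub	tag
EX_photon	 -> photon	0	100	
EX_co2	 -> co2	0	60	
EX_no3	 -> no3	0	1000	
carb	photon + co2 -> 2 triose	0	1000	carboxylation
oxy	photon + co2 -> triose	0	1000	oxygenation
starch_syn	triose -> starch	0	1000	starch_synthesis
suc_syn	triose -> sucrose	0	1000	sucrose_synthesis
biomass	0.5000000000000000 no3 + 2.5800000000000001 starch + sucrose -> 	0	1000	biomass
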