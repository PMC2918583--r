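order	kind	reaction	protein	compartments	citation
1	delete-link	RE3139	ACAA2		VLCFA beta-oxidation is peroxisomal
2	delete-link	RE3139	HADHA		VLCFA beta-oxidation is peroxisomal
3	delete-link	RE3139	HADHB		VLCFA beta-oxidation is peroxisomal
4	set-locations	RE3139		X	VLCFA beta-oxidation is peroxisomal
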