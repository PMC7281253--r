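base_id	description
fol	folate
dhf	7,8-dihydrofolate
thf	5,6,7,8-tetrahydrofolate
10fthf	10-formyltetrahydrofolate
5fthf	5-formyltetrahydrofolate
5mthf	5-methyltetrahydrofolate
methf	5,10-methenyltetrahydrofolate
mlthf	5,10-methylenetetrahydrofolate
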