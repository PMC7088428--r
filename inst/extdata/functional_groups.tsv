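group	members
aliphatic	AVLIG
hydroxyl	ST
sulfur	CM
aromatic	FWY
basic	KRH
acidic	DE
amide	NQ
imino	P
tiny	AG
charged	DEKRH
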