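group	members
hydrophobic	CFILMVW
hydrophilic	DEKNQR
neutral	AGHPSTY
polar	DEHKNQRSTY
nonpolar	ACFGILMPVW
small	ACDGNPSTV
aromatic	FHWY
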