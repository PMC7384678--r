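DRUG0006	DRUG0006
DRUG0001	DRUG0001
DRUG0012	DRUG0012
DRUG0014	DRUG0014
DRUG0002	DRUG0002
DRUG0011	DRUG0011
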