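DRUG0010	DIS0002
DRUG0011	DIS0002
DRUG0011	DIS0003
DRUG0004	DIS0004
DRUG0005	DIS0004
DRUG0006	DIS0004
DRUG0008	DIS0004
DRUG0009	DIS0004
DRUG0010	DIS0004
DRUG0011	DIS0004
DRUG0012	DIS0004
DRUG0013	DIS0004
DRUG0015	DIS0004
DRUG0004	DIS0005
DRUG0005	DIS0005
DRUG0009	DIS0005
DRUG0010	DIS0005
DRUG0011	DIS0005
DRUG0015	DIS0005
DRUG0010	DIS0006
DRUG0011	DIS0007
DRUG0010	DIS0010
DRUG0011	DIS0010
DRUG0005	DIS0011
DRUG0009	DIS0011
DRUG0010	DIS0011
DRUG0015	DIS0011
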