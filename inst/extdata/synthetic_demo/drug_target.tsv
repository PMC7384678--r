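XDRUG0003	TAR0002
DRUG0006	TAR0002
XDRUG0001	TAR0002
DRUG0001	TAR0002
DRUG0012	TAR0002
XDRUG0005	TAR0002
DRUG0011	TAR0002
XDRUG0004	TAR0002
XDRUG0002	TAR0002
XDRUG0005	TAR0003
DRUG0011	TAR0003
XDRUG0003	TAR0004
XDRUG0005	TAR0004
XDRUG0004	TAR0004
XDRUG0002	TAR0004
XDRUG0002	TAR0005
XDRUG0003	TAR0007
XDRUG0002	TAR0007
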