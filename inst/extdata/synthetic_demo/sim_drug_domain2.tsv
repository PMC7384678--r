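id	XDRUG0003	DRUG0006	XDRUG0001	DRUG0001	DRUG0012	DRUG0014	DRUG0002	XDRUG0005	DRUG0011	XDRUG0004	XDRUG0002	XDRUG0006
XDRUG0003	1.00000000000000000	0.40539699437546645	0.00000000000000000	0.44922380452002569	0.99981770568313733	0.16736803506362566	0.00000000000000000	0.30763170698796427	0.28599731369908499	0.14689950279634151	0.99989064584528686	0.98915142221916041
DRUG0006	0.40539699437546645	1.00000000000000000	0.00000000000000000	0.99882491565816189	0.38786909851559237	0.96909680650003682	0.00000000000000000	0.99452291100721180	0.99189990783921322	0.96377622156108966	0.39183399682458214	0.26671219460952555
XDRUG0001	0	0	0	0	0	0	0	0	0	0	0	0
DRUG0001	0.44922380452002569	0.99882491565816189	0.00000000000000000	0.99999999999999978	0.43208356126462028	0.95600282870926001	0.00000000000000000	0.98828883279894730	0.98457831313446298	0.94971768481529106	0.43596245144320528	0.31310752010943993
DRUG0012	0.99981770568313733	0.38786909851559237	0.00000000000000000	0.43208356126462028	1.00000000000000000	0.14851351209876471	0.00000000000000000	0.28940821501610392	0.26764936458692956	0.12798652538968816	0.99999073104994041	0.99177590680489647
DRUG0014	0.167368035063625659	0.969096806500036823	0.000000000000000000	0.956002828709260011	0.148513512098764705	0.999999999999999889	0.000000000000000000	0.989571750227317359	0.992580896786760536	0.999785215782117209	0.152769944747524256	0.020724919867281495
DRUG0002	0	0	0	0	0	0	0	0	0	0	0	0
XDRUG0005	0.30763170698796427	0.99452291100721180	0.00000000000000000	0.98828883279894730	0.28940821501610392	0.98957175022731736	0.00000000000000000	1.00000000000000000	0.99974336430110833	0.98637397186094000	0.29352683574276911	0.16451865436865706
DRUG0011	0.28599731369908499	0.99189990783921322	0.00000000000000000	0.98457831313446298	0.26764936458692956	0.99258089678676054	0.00000000000000000	0.99974336430110833	1.00000000000000000	0.98984784529164138	0.27179535769059771	0.14213107743028994
XDRUG0004	0.14689950279634151	0.96377622156108966	0.00000000000000000	0.94971768481529106	0.12798652538968816	0.99978521578211721	0.00000000000000000	0.98637397186094000	0.98984784529164138	1.00000000000000000	0.13225548599518505	0.00000000000000000
XDRUG0002	0.99989064584528686	0.39183399682458214	0.00000000000000000	0.43596245144320528	0.99999073104994041	0.15276994474752426	0.00000000000000000	0.29352683574276911	0.27179535769059771	0.13225548599518505	1.00000000000000000	0.99121566090542446
XDRUG0006	0.989151422219160414	0.266712194609525555	0.000000000000000000	0.313107520109439930	0.991775906804896468	0.020724919867281495	0.000000000000000000	0.164518654368657063	0.142131077430289937	0.000000000000000000	0.991215660905424456	1.000000000000000000
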