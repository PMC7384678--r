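id	DRUG0001	DRUG0002	DRUG0003	DRUG0004	DRUG0005	DRUG0006	DRUG0007	DRUG0008	DRUG0009	DRUG0010	DRUG0011	DRUG0012	DRUG0013	DRUG0014	DRUG0015
DRUG0001	1.000000000000000000	0.000000000000000000	0.100694976271818185	0.743835972629325659	0.422859759145494063	0.773240632076943046	1.000000000000000000	0.059941295632128154	0.430893182328885738	0.201210532002899178	0.939603944229088883	0.534311791636620681	0.998845434133162513	0.000000000000000000	0.315566069767947266
DRUG0002	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
DRUG0003	0.10069497627181818	0.00000000000000000	1.00000000000000000	0.73986570207674984	0.94416911120535985	0.70875117724506564	0.10069497627181818	0.99916417459067641	0.94120511483200975	0.99483020345199547	0.43513747033502659	0.89479367930319076	0.14837410238555371	0.99491734418172550	0.97585657459083830
DRUG0004	0.74383597262932566	0.00000000000000000	0.73986570207674984	1.00000000000000000	0.92020488526601862	0.99898116871317411	0.74383597262932566	0.71174692404013340	0.92364587380236940	0.80436051216691540	0.92766732514895367	0.96239853500117256	0.77508498729925268	0.66836221154594389	0.86894070783536637
DRUG0005	0.42285975914549406	0.00000000000000000	0.94416911120535985	0.92020488526601862	1.00000000000000000	0.90160219786017404	0.42285975914549406	0.92991247172388147	0.99996054168012771	0.97274548730391330	0.70747838129259555	0.99193435043766165	0.46590474950982802	0.90619513577121724	0.99333202534727050
DRUG0006	0.77324063207694305	0.00000000000000000	0.70875117724506564	0.99898116871317411	0.90160219786017404	0.99999999999999978	0.77324063207694305	0.67932155656208904	0.90540928730980341	0.77672800479171722	0.94357369753958842	0.94915911399613162	0.80281036621052859	0.63411270678425091	0.84572034203956614
DRUG0007	1.000000000000000000	0.000000000000000000	0.100694976271818185	0.743835972629325659	0.422859759145494063	0.773240632076943046	1.000000000000000000	0.059941295632128154	0.430893182328885738	0.201210532002899178	0.939603944229088883	0.534311791636620681	0.998845434133162513	0.000000000000000000	0.315566069767947266
DRUG0008	0.059941295632128154	0.000000000000000000	0.999164174590676413	0.711746924040133400	0.929912471723881473	0.679321556562089035	0.059941295632128154	0.999999999999999778	0.926608628092683517	0.989847517718185910	0.397969336788922323	0.875794904418104481	0.107825263340247987	0.998201903964293979	0.966112826388283885
DRUG0009	0.43089318232888574	0.00000000000000000	0.94120511483200975	0.92364587380236940	0.99996054168012771	0.90540928730980341	0.43089318232888574	0.92660862809268352	0.99999999999999978	0.97064725842162036	0.71372868638160125	0.99302120727023646	0.47374672216637270	0.90240293961316720	0.99226867251474404
DRUG0010	0.20121053200289918	0.00000000000000000	0.99483020345199547	0.80436051216691540	0.97274548730391330	0.77672800479171722	0.20121053200289918	0.98984751771818591	0.97064725842162036	1.00000000000000000	0.52432192118005005	0.93550882807577906	0.24803527077280962	0.97954801914511080	0.99299186549714569
DRUG0011	0.93960394422908888	0.00000000000000000	0.43513747033502659	0.92766732514895367	0.70747838129259555	0.94357369753958842	0.93960394422908888	0.39796933678892232	0.71372868638160125	0.52432192118005005	1.00000000000000000	0.79135266914878299	0.95496130408605195	0.34226368196047213	0.62128236621835708
DRUG0012	0.53431179163662068	0.00000000000000000	0.89479367930319076	0.96239853500117256	0.99193435043766165	0.94915911399613162	0.53431179163662068	0.87579490441810448	0.99302120727023646	0.93550882807577906	0.79135266914878299	1.00000000000000000	0.57430212628079669	0.84528747140725113	0.97070700279173494
DRUG0013	0.998845434133162513	0.000000000000000000	0.148374102385553708	0.775084987299252681	0.465904749509828020	0.802810366210528592	0.998845434133162513	0.107825263340247987	0.473746722166372702	0.248035270772809624	0.954961304086051954	0.574302126280796688	1.000000000000000000	0.048039553612979291	0.360786633663000234
DRUG0014	0.000000000000000000	0.000000000000000000	0.994917344181725505	0.668362211545943885	0.906195135771217242	0.634112706784250912	0.000000000000000000	0.998201903964293979	0.902402939613167199	0.979548019145110804	0.342263681960472133	0.845287471407251134	0.048039553612979291	1.000000000000000000	0.948903607123089743
DRUG0015	0.31556606976794727	0.00000000000000000	0.97585657459083830	0.86894070783536637	0.99333202534727050	0.84572034203956614	0.31556606976794727	0.96611282638828389	0.99226867251474404	0.99299186549714569	0.62128236621835708	0.97070700279173494	0.36078663366300023	0.94890360712308974	1.00000000000000000
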