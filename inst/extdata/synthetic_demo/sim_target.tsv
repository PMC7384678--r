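id	TAR0001	TAR0002	TAR0003	TAR0004	TAR0005	TAR0006	TAR0007	TAR0008	TAR0009	TAR0010
TAR0001	0.99999999999999978	0.97616710467954748	0.69577528365472241	0.78035413681557642	0.85328187290816015	0.71825953154496347	0.87402374783887427	0.90993146205592290	0.92702191835531877	0.79755816929915191
TAR0002	0.97616710467954748	0.99999999999999978	0.83506979870062525	0.62604507021722777	0.71978050408829541	0.55014400959939302	0.74774674266850161	0.97825618085906174	0.98631244309234489	0.64763431639430968
TAR0003	0.695775283654722410	0.835069798700625254	1.000000000000000000	0.093796252847290651	0.219156043784722282	0.000000000000000000	0.259133878372755755	0.931012171837037328	0.914351398406232807	0.121636911796357633
TAR0004	0.780354136815576416	0.626045070217227773	0.093796252847290651	1.000000000000000000	0.991944424729904628	0.995591413659141167	0.985889203492599231	0.450704502548853081	0.488899225355575950	0.999607898462461009
TAR0005	0.85328187290816015	0.71978050408829541	0.21915604378472228	0.99194442472990463	1.00000000000000000	0.97568982185560849	0.99915239078220530	0.56015214897096910	0.59546354066303941	0.99510246051737994
TAR0006	0.71825953154496347	0.55014400959939302	0.00000000000000000	0.99559141365914117	0.97568982185560849	1.00000000000000000	0.96584141197170348	0.36498813116495049	0.40492162233272561	0.99257466302976183
TAR0007	0.87402374783887427	0.74774674266850161	0.25913387837275575	0.98588920349259923	0.99915239078220530	0.96584141197170348	1.00000000000000000	0.59377744685764311	0.62802949551627241	0.99018995873507787
TAR0008	0.90993146205592290	0.97825618085906174	0.93101217183703733	0.45070450254885308	0.56015214897096910	0.36498813116495049	0.59377744685764311	1.00000000000000000	0.99906386745592046	0.47552341672799031
TAR0009	0.92702191835531877	0.98631244309234489	0.91435139840623281	0.48889922535557595	0.59546354066303941	0.40492162233272561	0.62802949551627241	0.99906386745592046	1.00000000000000000	0.51313382323918477
TAR0010	0.79755816929915191	0.64763431639430968	0.12163691179635763	0.99960789846246101	0.99510246051737994	0.99257466302976183	0.99018995873507787	0.47552341672799031	0.51313382323918477	1.00000000000000000
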