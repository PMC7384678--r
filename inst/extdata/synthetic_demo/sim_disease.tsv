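id	DIS0001	DIS0002	DIS0003	DIS0004	DIS0005	DIS0006	DIS0007	DIS0008	DIS0009	DIS0010	DIS0011	DIS0012
DIS0001	0	0	0	0	0	0	0	0	0	0	0	0
DIS0002	0.00000000000000000	0.99999999999999989	0.96498664929355560	0.81632851953938268	0.44233606908713657	0.45502771520780427	0.94399351300848822	0.00000000000000000	0.57308227962750302	0.89975308045599933	0.28662495877918226	0.28662495877918226
DIS0003	0.000000000000000000	0.964986649293555598	1.000000000000000000	0.636245400526275540	0.191605704681561323	0.205524369136795865	0.824391906603878288	0.000000000000000000	0.338063284285359256	0.753782595667190192	0.025295570534176585	0.025295570534176585
DIS0004	0.00000000000000000	0.81632851953938268	0.63624540052627554	1.00000000000000000	0.87910086928774067	0.88578097448727422	0.96119203638204376	0.00000000000000000	0.94115541804711644	0.98655307240023404	0.78733406708862164	0.78733406708862164
DIS0005	0.00000000000000000	0.44233606908713657	0.19160570468156132	0.87910086928774067	1.00000000000000000	0.99989915923216743	0.71349039535353109	0.00000000000000000	0.98846108378349451	0.78937772676051710	0.98600470341442947	0.98600470341442947
DIS0006	0.00000000000000000	0.45502771520780427	0.20552436913679586	0.88578097448727422	0.99989915923216743	1.00000000000000000	0.72336866340101158	0.00000000000000000	0.99051251938025620	0.79801629428121490	0.98353770131494034	0.98353770131494034
DIS0007	0.00000000000000000	0.94399351300848822	0.82439190660387829	0.96119203638204376	0.71349039535353109	0.72336866340101158	0.99999999999999989	0.00000000000000000	0.81139074543414769	0.99335715099658595	0.58669176683378221	0.58669176683378221
DIS0008	0	0	0	0	0	0	0	0	0	0	0	0
DIS0009	0.00000000000000000	0.57308227962750302	0.33806328428535926	0.94115541804711644	0.98846108378349451	0.99051251938025620	0.81139074543414769	0.00000000000000000	1.00000000000000000	0.87326087019503496	0.94937373879820552	0.94937373879820552
DIS0010	0.00000000000000000	0.89975308045599933	0.75378259566719019	0.98655307240023404	0.78937772676051710	0.79801629428121490	0.99335715099658595	0.00000000000000000	0.87326087019503496	0.99999999999999989	0.67598097525038858	0.67598097525038858
DIS0011	0.000000000000000000	0.286624958779182260	0.025295570534176585	0.787334067088621636	0.986004703414429473	0.983537701314940338	0.586691766833782213	0.000000000000000000	0.949373738798205524	0.675980975250388583	1.000000000000000000	1.000000000000000000
DIS0012	0.000000000000000000	0.286624958779182260	0.025295570534176585	0.787334067088621636	0.986004703414429473	0.983537701314940338	0.586691766833782213	0.000000000000000000	0.949373738798205524	0.675980975250388583	1.000000000000000000	1.000000000000000000
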