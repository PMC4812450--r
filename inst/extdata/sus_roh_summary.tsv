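sample	species	group	sex	pedigree_F	n_rohs	mean_length_kb	pi
02M01	Sus cebifrons	negros	M	0	34	761.43	12.5
02M02	Sus cebifrons	negros	M	0	75	1764.21	12.1
01F01	Sus cebifrons	panay	F	0.1875	110	2245.32	11.9
Kb16508	Sus cebifrons	panay	M	0.0625	132	1420.68	12.4
Kb16637	Sus cebifrons	panay	F	0	144	1860.76	12.4
Kb17528	Sus cebifrons	panay	F	0.25	193	2867.06	12.0
Kb14130	Sus cebifrons	panay	F	0	130	2563.13	12.2
Sus verrucosus	Sus verrucosus	other	U	NA	275	3829.13	6.3
Sus barbatus	Sus barbatus	other	U	NA	11	1551.82	26.4
Sus celebensis	Sus celebensis	other	U	NA	36	2719.72	23.2
Asian domestic	Sus scrofa	other	M	NA	271	2796.31	30.9
Asian wild boar 1	Sus scrofa	other	U	NA	155	1966.39	28.9
Asian wild boar 2	Sus scrofa	other	U	NA	44	2120.00	33.9
Asian wild boar (Japan)	Sus scrofa	other	U	NA	1172	1573.41	17.5
European domestic	Sus scrofa	other	F	NA	493	1859.01	28.4
European wild boar 1	Sus scrofa	other	M	NA	592	1912.82	16.2
European wild boar 2	Sus scrofa	other	U	NA	708	1401.60	18.4
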