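trait	category	term	effect_allele	beta
hair	black_dark_brown	(reference)	NA	0
hair	brown_light_brown	(Intercept)	NA	0.09147535077608761
hair	brown_light_brown	rs1805005	alt	-0.2395720934532483
hair	brown_light_brown	rs1805006	alt	0.17364402848106042
hair	brown_light_brown	rs2228479	alt	0.03910501777833434
hair	brown_light_brown	rs11547464	alt	-0.34792764312661684
hair	brown_light_brown	rs1805008	alt	0.2036302911082207
hair	brown_light_brown	rs885479	alt	0.3192606921361099
hair	brown_light_brown	rs1800407	alt	-0.26074440284249506
hair	brown_light_brown	rs12913832	alt	-0.2131128532406366
hair	brown_light_brown	rs12896399	alt	0.03683174098697549
hair	brown_light_brown	rs1393350	alt	0.08235832019781678
hair	brown_light_brown	rs12203592	alt	-0.21341847384292223
hair	brown_light_brown	rs1042602	alt	-0.06979706971385655
hair	brown_light_brown	rs4959270	alt	-0.04914656372251153
hair	brown_light_brown	rs28777	alt	0.15670947602105229
hair	brown_light_brown	rs683	alt	-0.23878351131031325
hair	brown_light_brown	rs2402130	alt	-0.16491054209309042
hair	brown_light_brown	rs16891982	alt	0.11965160012854367
hair	brown_light_brown	rs2378249	alt	0.15247523618775422
hair	blonde_dark_blonde	(Intercept)	NA	-2.1112727509939044
hair	blonde_dark_blonde	rs1805005	alt	0.09395489107302188
hair	blonde_dark_blonde	rs1805006	alt	-0.17779532836023867
hair	blonde_dark_blonde	rs2228479	alt	0.033318351615346124
hair	blonde_dark_blonde	rs11547464	alt	-0.01322607837879632
hair	blonde_dark_blonde	rs1805008	alt	0.26105850062616376
hair	blonde_dark_blonde	rs885479	alt	0.05209535362572842
hair	blonde_dark_blonde	rs1800407	alt	-0.20369933082606126
hair	blonde_dark_blonde	rs12913832	alt	1.1623648135080917
hair	blonde_dark_blonde	rs12896399	alt	-0.036611645858064326
hair	blonde_dark_blonde	rs1393350	alt	-0.12680411474254352
hair	blonde_dark_blonde	rs12203592	alt	0.27195024822594677
hair	blonde_dark_blonde	rs1042602	alt	0.2765100026343402
hair	blonde_dark_blonde	rs4959270	alt	-5.423529304444735e-4
hair	blonde_dark_blonde	rs28777	alt	0.5304288242417756
hair	blonde_dark_blonde	rs683	alt	0.31816434494926044
hair	blonde_dark_blonde	rs2402130	alt	0.23134984500146374
hair	blonde_dark_blonde	rs16891982	alt	0.8389928334541389
hair	blonde_dark_blonde	rs2378249	alt	-0.006415994652877877
hair	red	(Intercept)	NA	-3.308733722298267
hair	red	rs1805005	alt	1.8053274306667035
hair	red	rs1805006	alt	2.0130780807900694
hair	red	rs2228479	alt	1.315164366928416
hair	red	rs11547464	alt	1.435422218390603
hair	red	rs1805008	alt	1.7184864660556745
hair	red	rs885479	alt	0.9591025984874418
hair	red	rs1800407	alt	0.10620971713125746
hair	red	rs12913832	alt	-0.1703421932383797
hair	red	rs12896399	alt	0.1735813654541639
hair	red	rs1393350	alt	-0.1368199657936172
hair	red	rs12203592	alt	0.13890460566967977
hair	red	rs1042602	alt	0.2410980130564387
hair	red	rs4959270	alt	0.07122217733076762
hair	red	rs28777	alt	-0.19512194546557898
hair	red	rs683	alt	0.044610991043278064
hair	red	rs2402130	alt	-0.009460090894533901
hair	red	rs16891982	alt	0.09866586239767443
hair	red	rs2378249	alt	0.06391054112718794
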