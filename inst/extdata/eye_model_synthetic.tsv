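trait	category	term	effect_allele	beta
eye	blue	(reference)	NA	0
eye	intermediate	(Intercept)	NA	-1.8336142557625879
eye	intermediate	rs12913832	alt	1.0749525287744857
eye	intermediate	rs1800407	alt	0.3725944992536182
eye	intermediate	rs12896399	alt	0.2025721601287495
eye	intermediate	rs16891982	alt	0.40336107569023644
eye	intermediate	rs1393350	alt	0.33724703388388533
eye	intermediate	rs12203592	alt	0.18775318808640928
eye	brown	(Intercept)	NA	-2.6732975062757136
eye	brown	rs12913832	alt	2.30614341410905
eye	brown	rs1800407	alt	0.7232698487502188
eye	brown	rs12896399	alt	0.3238056217843348
eye	brown	rs16891982	alt	0.865231544668628
eye	brown	rs1393350	alt	0.601102641491822
eye	brown	rs12203592	alt	0.32442179687008665
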