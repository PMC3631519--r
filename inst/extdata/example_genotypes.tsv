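marker_id	chrom	position	chromosome_class	ref	alt	tags	S1	S2	S3
auto_1	1	100	autosomal	A	G		0	1	2
auto_2	2	200	autosomal	C	T		2	NA	1
x_1	X	300	X_specific	A	C		1	0	2
y_1	Y	400	Y	G	A		1	0	NA
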