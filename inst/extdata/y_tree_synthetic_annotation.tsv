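node	marker_id	derived_allele	geography
ROOT	NA	NA	NA
A	y_1	alt	Africa
A	y_21	alt	Africa
A	y_41	alt	Africa
A1	y_2	alt	Africa
A1	y_22	alt	Africa
A1	y_42	alt	Africa
A2	y_3	alt	Africa
A2	y_23	alt	Africa
A2	y_43	alt	Africa
A1a	y_4	alt	Africa
A1a	y_24	alt	Africa
A1a	y_44	alt	Africa
B	y_5	alt	Western Eurasia
B	y_25	alt	Western Eurasia
B	y_45	alt	Western Eurasia
B1	y_6	alt	Western Eurasia
B1	y_26	alt	Western Eurasia
B1	y_46	alt	Western Eurasia
B2	y_7	alt	Western Eurasia
B2	y_27	alt	Western Eurasia
B2	y_47	alt	Western Eurasia
B1a	y_8	alt	Western Eurasia
B1a	y_28	alt	Western Eurasia
B1a	y_48	alt	Western Eurasia
C	y_9	alt	East Asia
C	y_29	alt	East Asia
C	y_49	alt	East Asia
C1	y_10	alt	East Asia
C1	y_30	alt	East Asia
C1	y_50	alt	East Asia
C2	y_11	alt	East Asia
C2	y_31	alt	East Asia
C1a	y_12	alt	East Asia
C1a	y_32	alt	East Asia
D	y_13	alt	South Asia
D	y_33	alt	South Asia
D1	y_14	alt	South Asia
D1	y_34	alt	South Asia
D2	y_15	alt	South Asia
D2	y_35	alt	South Asia
D1a	y_16	alt	South Asia
D1a	y_36	alt	South Asia
E	y_17	alt	Americas
E	y_37	alt	Americas
E1	y_18	alt	Americas
E1	y_38	alt	Americas
E2	y_19	alt	Americas
E2	y_39	alt	Americas
E1a	y_20	alt	Americas
E1a	y_40	alt	Americas
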