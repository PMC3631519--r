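node	marker_id	derived_allele	geography
ROOT	NA	NA	NA
A	mt_1	alt	Africa
A	mt_21	alt	Africa
A	mt_41	alt	Africa
A1	mt_2	alt	Africa
A1	mt_22	alt	Africa
A1	mt_42	alt	Africa
A2	mt_3	alt	Africa
A2	mt_23	alt	Africa
A2	mt_43	alt	Africa
A1a	mt_4	alt	Africa
A1a	mt_24	alt	Africa
A1a	mt_44	alt	Africa
B	mt_5	alt	Western Eurasia
B	mt_25	alt	Western Eurasia
B	mt_45	alt	Western Eurasia
B1	mt_6	alt	Western Eurasia
B1	mt_26	alt	Western Eurasia
B1	mt_46	alt	Western Eurasia
B2	mt_7	alt	Western Eurasia
B2	mt_27	alt	Western Eurasia
B2	mt_47	alt	Western Eurasia
B1a	mt_8	alt	Western Eurasia
B1a	mt_28	alt	Western Eurasia
B1a	mt_48	alt	Western Eurasia
C	mt_9	alt	East Asia
C	mt_29	alt	East Asia
C	mt_49	alt	East Asia
C1	mt_10	alt	East Asia
C1	mt_30	alt	East Asia
C1	mt_50	alt	East Asia
C2	mt_11	alt	East Asia
C2	mt_31	alt	East Asia
C1a	mt_12	alt	East Asia
C1a	mt_32	alt	East Asia
D	mt_13	alt	South Asia
D	mt_33	alt	South Asia
D1	mt_14	alt	South Asia
D1	mt_34	alt	South Asia
D2	mt_15	alt	South Asia
D2	mt_35	alt	South Asia
D1a	mt_16	alt	South Asia
D1a	mt_36	alt	South Asia
E	mt_17	alt	Americas
E	mt_37	alt	Americas
E1	mt_18	alt	Americas
E1	mt_38	alt	Americas
E2	mt_19	alt	Americas
E2	mt_39	alt	Americas
E1a	mt_20	alt	Americas
E1a	mt_40	alt	Americas
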