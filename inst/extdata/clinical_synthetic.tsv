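patient_id	subtype	antibody_class	ck_baseline	mmt_baseline	mmt_followup	tis	weeks_observed
P01	DM	MSA	1350	62	74	65	9
P02	DM	MSA	6500	55	70	57.5	9
P03	DM	MSA	2900	60	71	50	9
P04	DM	MSA	985	64	72	47.5	9
P05	DM	MSA	510	58	66	45	9
P06	DM	MSA	1600	63	69	42.5	9
P07	DM	MAA	820	66	70	40	9
P08	DM	MSA	1199	61	66	40	9
P09	NM/OM	MSA	2100	59	62	37.5	9
P10	NM/OM	MSA	390	65	67	35	6
P11	NM/OM	seronegative	245	68	69	32.5	9
P12	NM/OM	MSA	3800	57	59	30	6
P13	NM/OM	MAA	180	70	71	27.5	9
P14	IMNM	MSA	7400	54	56	25	6
P15	IMNM	MSA	5500	56	57	20	5
P16	IMNM	seronegative	4600	60	60	15	6
P17	IMNM	seronegative	1100	62	61	10	7
P18	IMNM	seronegative	640	67	66	5	6
P19	ASS	seronegative	150	69	68	0	4
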