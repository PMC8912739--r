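outcome	contrast	or	or_low	or_high	gre	gre_low	gre_high
all	multi_wk	1.19	1.01	1.40	13.3	0.6	26.0
all	daily	1.41	1.18	1.69	26.2	12.0	40.4
all	gt1_day	1.74	1.31	2.33	42.3	19.6	64.9
colon	multi_wk	1.17	0.98	1.41	12.8	-2.3	28.0
colon	daily	1.32	1.08	1.61	22.7	5.9	39.6
colon	gt1_day	1.76	1.28	2.43	46.3	19.1	73.4
proximal	multi_wk	1.28	1.03	1.60	21.8	2.1	41.5
proximal	daily	1.40	1.10	1.78	29.7	7.8	51.6
proximal	gt1_day	1.73	1.17	2.56	48.4	12.9	83.9
distal	multi_wk	1.06	0.83	1.37	4.2	-13.6	21.9
distal	daily	1.22	0.93	1.61	14.2	-5.3	33.7
distal	gt1_day	1.76	1.17	2.65	40.4	10.5	70.4
rectum	multi_wk	1.26	1.00	1.60	17.6	-0.6	35.9
rectum	daily	1.64	1.28	2.12	37.8	17.4	58.1
rectum	gt1_day	1.82	1.23	2.67	45.7	15.5	75.9
stage_I_III	multi_wk	1.18	0.99	1.40	12.6	-0.6	25.8
stage_I_III	daily	1.37	1.14	1.66	24.0	9.4	38.7
stage_I_III	gt1_day	1.76	1.31	2.38	43.1	19.7	66.6
stage_IV	multi_wk	1.31	0.94	1.85	20.6	-5.6	46.8
stage_IV	daily	1.66	1.16	2.40	38.7	9.7	67.7
stage_IV	gt1_day	1.80	1.04	3.07	44.9	2.5	87.2
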