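# corrected=false
sample_id	ASV1	ASV2	ASV3	ASV4	ASV5
CA_E001	40	20	30	700	210
CA_E002	36	24	28	690	222
CA_E003	44	16	33	680	227
CA_E004	50	25	30	640	255
CA_E005	240	120	90	430	120
CA_E006	8	4	10	560	418
CA_E007	30	15	25	620	310
CB_E001	50	25	40	660	225
CB_E002	55	20	38	652	235
CB_E003	48	27	42	648	235
CB_E004	52	24	39	655	230
CB_E005	49	26	41	662	222
CB_E006	53	22	40	650	235
CB_E007	51	25	38	645	241
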