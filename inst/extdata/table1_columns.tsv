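column_id	treatment	temperature_c	sacrifice_stage	harvest_day	n_total	n_effluent	tm_start_day	tm_end_day	ct_days
C01	treated	30	rebound	148	47	44	43	50	45
C02	nontreated	30	sulfidogenesis	148	47	44			
C03	treated	30	mitigation	113	38	35	43	47	45
C04	treated	30	mitigation	73	27	24	43	54	45;47
C05	nontreated	30	sulfidogenesis	73	27	24			
C06	treated	30	mitigation	68	25	22	43	47	45
C07	nontreated	19	sulfidogenesis	68	25	22			
C08	nontreated	30	sulfidogenesis	68	25	22			
C09	nontreated	19	sulfidogenesis	68	25	22			
C10	treated	19	mitigation	68	25	22	43	52	45;47
C11	nontreated	30	sulfidogenesis	113	38	35			
C12	nontreated	30	sulfidogenesis	148	47	44			
C13	treated	30	mitigation	113	38	35	43	47	45;47
C14	treated	19	mitigation	73	27	24	43	57	45;47;52
C15	treated	30	rebound	148	47	44	43	47	45;47
C16	nontreated	30	sulfidogenesis	148	47	44			
C17	nontreated	30	sulfidogenesis	113	38	35			
C18	treated	30	rebound	148	47	44	43	47	43;45
C19	treated	30	rebound	148	47	44	43	52	45;47
C20	nontreated	30	none		44	44			
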