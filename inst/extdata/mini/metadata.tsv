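sample_id	column_id	time_point	sample_type	section	treatment	temperature_c
CA_E001	CA	01/01/2020	effluent	none	treated	30
CA_E002	CA	01/11/2020	effluent	none	treated	30
CA_E003	CA	01/21/2020	effluent	none	treated	30
CA_E004	CA	01/29/2020	effluent	none	treated	30
CA_E005	CA	02/01/2020	effluent	none	treated	30
CA_E006	CA	02/04/2020	effluent	none	treated	30
CA_E007	CA	02/20/2020	effluent	none	treated	30
CB_E001	CB	01/01/2020	effluent	none	nontreated	30
CB_E002	CB	01/11/2020	effluent	none	nontreated	30
CB_E003	CB	01/21/2020	effluent	none	nontreated	30
CB_E004	CB	01/29/2020	effluent	none	nontreated	30
CB_E005	CB	02/01/2020	effluent	none	nontreated	30
CB_E006	CB	02/04/2020	effluent	none	nontreated	30
CB_E007	CB	02/20/2020	effluent	none	nontreated	30
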