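column_id	time_point	cells_per_ml
CA	01/01/2020	8100000
CA	01/11/2020	9e+06
CA	01/21/2020	7600000
CA	01/29/2020	8800000
CA	02/01/2020	1.5e+07
CA	02/04/2020	6400000
CA	02/20/2020	7900000
CB	01/01/2020	7700000
CB	01/11/2020	8400000
CB	01/21/2020	8900000
CB	01/29/2020	8200000
CB	02/01/2020	7500000
CB	02/04/2020	8800000
CB	02/20/2020	9100000
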