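column_id	time_point	sulfide_mm
CA	01/01/2020	0.2
CA	01/11/2020	1.5
CA	01/21/2020	2.8
CA	01/29/2020	1.9
CA	02/01/2020	1.4
CA	02/04/2020	0.5
CA	02/20/2020	2.2
CB	01/01/2020	0.1
CB	01/11/2020	0.8
CB	01/21/2020	1.6
CB	01/29/2020	2.2
CB	02/01/2020	2.5
CB	02/04/2020	2.9
CB	02/20/2020	3.1
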