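taxon_id	genome_label	is_srb	copy_number	has_dsr
ASV1	Desulfobacula toluolica Tol2	TRUE	2	TRUE
ASV2	Desulfobacula toluolica Tol2	TRUE	1	TRUE
ASV3	Desulfarculus baarsii DSM 2075	TRUE	3	TRUE
ASV4	Marinobacter sp. MB-1	FALSE	4	FALSE
ASV5	Thauera sp. NRB-1	FALSE	1	FALSE
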