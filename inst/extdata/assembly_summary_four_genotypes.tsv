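genotype	total_reads	assembled_reads	n_contigs	total_length_mb	mean_len_bp	sd_len_bp	min_len_bp	max_len_bp
Ogle1040	283478	231057	32245	18.09	561	205	41	2217
TAM_O-301	381397	307751	42147	24.70	586	217	40	4303
Gem	180447	137743	23681	14.20	598	238	43	4229
HiFi	235589	188015	29036	16.40	564	220	42	4416
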