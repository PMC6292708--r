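chrom	size_bp	n_snp	h2c	se
chr1	156000000	1099	0.020759719135318117	0.019890701345100931
chr2	119000000	836	0.0078882374079780847	0.017348198753761153
chr3	116000000	828	0.032276414858790382	0.017264993483925791
chr4	73000000	509	0.020313980864662323	0.013536617007214173
chr5	64000000	484	0.0014680645501985237	0.013199999999999998
chr6	37000000	261	0.0060839260993763898	0.0096932966528421056
chr7	39000000	288	0.0104899941915725	0.010182337649086283
chr8	32000000	241	0.010842536322246764	0.0093145048177560134
chr9	27000000	198	0.0036810622213579516	0.0084427483676821728
chr10	21000000	152	9.9999999999999995e-07	0.0073972968035627704
chr11	22000000	153	0.010477509433494514	0.0074215901261117882
chr12	21000000	148	0.001555241335967553	0.0072993150363578627
chr13	18000000	109	0.014944130567432254	0.0062641839053463296
chr14	17000000	108	0.0065359529159700717	0.0062353829072479576
chr15	15000000	117	9.9999999999999995e-07	0.006489992295835181
chr16	9900000	62	9.9999999999999995e-07	0.0047244047244070862
chr17	12000000	101	0.011995527654258615	0.0060299253726725337
chr18	11000000	70	0.0019381691158337642	0.005019960159204453
chr19	11600000	78	0.012797978251247465	0.0052990565197967082
chr20	15500000	106	9.9999999999999995e-07	0.0061773780845922003
chr21	7200000	48	0.0065357377254591578	0.004156921938165305
chr22	5200000	40	0.0011800670459924214	0.0037947331922020553
chr23	6900000	57	9.9999999999999995e-07	0.0045299006611624493
chr24	8100000	47	0.00081527172335951097	0.0041133927602406261
chr25	2200000	16	0.003735682928376627	0.0023999999999999998
chr26	6800000	40	0.0011324975630977803	0.0037947331922020553
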