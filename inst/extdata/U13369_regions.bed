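45S	0	3656	5ETS	1
45S	3656	5527	18S	1
45S	5527	6622	ITS1	1
45S	6622	6779	5.8S	1
45S	6779	7934	ITS2	1
45S	7934	12969	28S	1
45S	12969	13314	3ETS	1
45S	13314	42999	IGS	0
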