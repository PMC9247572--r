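sample_id	subject	state	age	height	weight	education	flavor	fruit_veg	smoking	drinking	exercise	sleep
S01_BT	S01	BT	34	172.1	68.0	2	3	1	1	0	1	2
S01_AT	S01	AT	34	172.1	68.0	2	3	1	1	0	1	2
S02_BT	S02	BT	47	168.5	75.2	1	2	2	0	1	2	1
S02_AT	S02	AT	47	168.5	75.2	1	2	2	0	1	2	1
S03_BT	S03	BT	26	175.0	61.3	3	1	3	0	0	3	3
S03_AT	S03	AT	26	175.0	61.3	3	1	3	0	0	3	3
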