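node_id	n_bt	n_at	core_at	exclusive_at	jaccard	nesh	delbet
ASV 37	1	11	6	11	0.000	2.650	1.000
ASV 136	4	13	7	9	0.308	1.985	0.723
ASV 86	2	10	5	9	0.091	2.327	0.523
ASV 40	4	4	2	3	0.143	1.486	0.448
ASV 81	3	6	3	4	0.286	1.552	0.441
ASV 174	1	5	3	5	0.000	2.167	0.320
ASV 36	3	7	4	7	0.000	2.167	0.316
ASV 57	3	3	2	2	0.200	1.333	0.274
ASV 25	1	5	3	4	0.200	1.867	0.156
ASV 125	1	11	7	11	0.000	2.650	0.144
ASV 231	5	9	6	9	0.000	2.243	0.088
ASV 26	1	2	2	1	0.500	1.067	0.077
ASV 72	2	6	5	5	0.143	1.905	0.064
ASV 234	4	3	2	2	0.167	1.300	0.063
ASV 9	3	4	3	3	0.167	1.533	0.011
ASV 178	1	4	4	4	0.000	2.067	0.003
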