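stratum	level	case_n	control_n
loss	5	5	0
loss	4	52	9
loss	3	78	7
loss	2	115	365
loss	1	149	307
loss	0	435	1501
loss	NA	1	358
gain	5	18	1
gain	4	102	25
gain	3	176	52
gain	2	288	354
gain	1	261	300
gain	0	509	746
gain	NA	3	384
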