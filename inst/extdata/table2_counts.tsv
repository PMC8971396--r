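level	total	cns	non_cns	no_phenotype	absent
5	75	58	3	14	2
4	447	121	29	297	11
3	1079	241	91	747	135
2	3407	603	284	2520	644
1	3290	489	409	2392	453
0	10461	715	1389	8357	2734
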