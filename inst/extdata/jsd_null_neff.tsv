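df	N	n_eff
1	50	16.11
1	100	23.479
1	200	30.849
1	500	40.59
1	1000	47.96
1	2000	55.329
1	5000	65.071
1	10000	72.44
1	20000	79.809
1	50000	89.551
3	50	16.169
3	100	24.681
3	200	33.194
3	500	44.447
3	1000	52.96
3	2000	61.473
3	5000	72.726
3	10000	81.239
3	20000	89.751
3	50000	101.005
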