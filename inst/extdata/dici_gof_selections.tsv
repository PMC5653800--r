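subject	dici_order	dici_comp	gof_order	gof_comp
1	50	18	20	18
2	30	15	50	35
3	60	34	60	34
4	50	21	50	21
5	40	20	50	43
6	60	16	30	13
7	60	44	60	44
8	40	37	30	11
9	50	40	50	40
10	50	46	50	46
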