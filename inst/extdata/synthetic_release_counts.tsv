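condition	replicate	supernatant	pellet
no-factor	1	1319	9024
no-factor	2	1254	8335
no-factor	3	1225	8492
mtRF1a_UAG	1	8366	1914
mtRF1a_UAG	2	8017	1699
mtRF1a_UAG	3	7633	1572
mtRF1a_AGA	1	1260	9287
mtRF1a_AGA	2	1223	8477
mtRF1a_AGA	3	1316	7696
mtRF1a_AGG	1	1420	8671
mtRF1a_AGG	2	1089	7992
mtRF1a_AGG	3	1231	8657
mtRF1_UAG	1	1540	9008
mtRF1_UAG	2	1556	9305
mtRF1_UAG	3	1525	8428
mtRF1_AGA	1	5443	5195
mtRF1_AGA	2	5177	5329
mtRF1_AGA	3	5263	5695
mtRF1_AGG	1	3936	6894
mtRF1_AGG	2	3386	6189
mtRF1_AGG	3	4002	6345
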