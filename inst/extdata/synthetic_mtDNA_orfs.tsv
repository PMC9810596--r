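gene	start	end	strand	polya_completion
ND1	5	245	+	0
ND2	269	538	+	1
COX1	568	1018	+	0
COX2	1045	1255	+	0
ATP8	1277	1397	+	0
ATP6	1351	1575	+	1
COX3	1601	1839	+	2
ND3	1860	1978	+	2
ND4L	2001	2106	+	0
ND4	2099	2457	+	2
ND5	2482	2902	+	0
ND6	2930	3110	-	0
CYTB	3134	3434	+	0
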