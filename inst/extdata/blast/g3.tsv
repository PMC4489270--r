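# BLASTP 2.x, toy fixture: query proteome vs genome g3
pA	g3_hitA	38.0	110	60	5	3	113	2	111	1e-08	50.0
pB	g3_hitB	48.0	170	75	3	1	170	1	170	1e-22	75.0
pC	g3_hitC	36.0	85	50	4	2	86	1	85	1e-08	50.0
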