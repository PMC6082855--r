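# synthetic CTCF loop calls (anchor midpoints map to beads at 1200 bp/bead)
chrS	1000	1400	chrS	7000	7400	loop1	.	+	-
chrS	9500	9900	chrS	15500	15900	loop2	.	+	-
chrS	17200	17600	chrS	22800	23200	loop3	.	+	-
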