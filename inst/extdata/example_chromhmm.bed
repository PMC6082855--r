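# synthetic ChromHMM-style segmentation (state numbers 1-15 in the name field)
chrS	0	3600	5_TxnElongation
chrS	3600	8400	13_Heterochrom
chrS	8400	10800	2_PromoterFlanking
chrS	10800	16800	14_Repetitive
chrS	16800	19200	7_Enhancer
chrS	19200	24000	12_Repressed
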