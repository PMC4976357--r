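name	oligo
insert1_forward	CAACCGATTATTTGGAGACTATGGAAGG
insert1_reverse	AAACCCTTCCATAGTCTCCAAATAATC
insert2_forward	CACCCCACTCTAGTACTATATCTGTCA
insert2_reverse	AAACTGACAGATATAGTACTAGAGTGG
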