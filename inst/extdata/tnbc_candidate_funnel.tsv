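sample	allele	n_predicted	n_bound	n_immunogenic	n_displayed
SW1360	HLA-A*24:02	4	2	0	NA
SW2163	HLA-A*02:01	10	9	4	NA
SW2163	HLA-A*24:02	9	4	0	NA
SW2183	HLA-A*02:01	14	14	10	NA
SW2183	HLA-A*24:02	20	8	0	NA
SW2388	HLA-A*03:01	9	7	0	NA
MDA-MB-231	HLA-A*02:01	27	21	16	1
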