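# gene_id accession name start_aa end_aa evalue
G0001 PF01183 Glyco_hydro_25 6 176 9.54e-07
G0001 PF08460 SH3_5 225 294 1.56e-06
G0002 PF01183 Glyco_hydro_25 6 165 6.35e-06
G0002 PF08460 SH3_5 211 275 3.91e-06
G0003 PF01510 Amidase_2 10 122 1.11e-06
G0003 PF05257 CHAP 192 266 2.21e-06
G0003 PF08460 SH3_5 296 365 7.11e-06
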