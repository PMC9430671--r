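gene_id	host_genus	family	source
G0001	Streptococcus	endolysin	synthetic
G0002	Staphylococcus	endolysin	synthetic
G0003	Streptococcus	endolysin	synthetic
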