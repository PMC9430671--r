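gene_id	has_itss	itss_codon	planted_class	intended_filter_outcome	realized_status	realized_codon	collision
G0001	FALSE	NA	group2	none	retained	192	TRUE
G0002	TRUE	206	group2_strong	retain	retained	206	FALSE
G0003	FALSE	NA	group1	none	excluded	343	FALSE
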