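protein_id	term_id
Protein1	IPR2
Protein1	IPR3
Protein1	IPR4
Protein2	IPR1
Protein2	IPR2
Protein2	IPR5
Protein3	IPR6
Protein4	IPR1
Protein4	IPR2
Protein4	IPR3
Protein4	IPR6
Protein5	IPR2
Protein5	IPR4
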