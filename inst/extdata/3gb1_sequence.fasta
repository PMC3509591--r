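>3GB1_seq protein G B1 domain, 56 residues
MTYKLILNGKTLKGETTTEAVDAATAEKVFKQYANDNGVDGEWTYDDATKTFTVTE
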