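# Synthetic 180-degree kissing-loop sequence pairs (7 nt loop, seq_b = reverse complement of seq_a).
# Replace with an experimentally validated list for wet-lab designs.
id	seq_a	seq_b
KL01	UACGCGC	GCGCGUA
KL02	AAUCUUG	CAAGAUU
KL03	GAAGCAG	CUGCUUC
KL04	AACUCCG	CGGAGUU
KL05	UAUCUGG	CCAGAUA
KL06	UUCCCUU	AAGGGAA
KL07	ACACUCU	AGAGUGU
KL08	GCGAAUU	AAUUCGC
KL09	UUUCGUA	UACGAAA
KL10	UGUUUCA	UGAAACA
KL11	AAGCAUA	UAUGCUU
KL12	ACCAGGA	UCCUGGU
KL13	CACCUAC	GUAGGUG
KL14	UUUCAUA	UAUGAAA
KL15	UCGCACA	UGUGCGA
KL16	CGUUGAA	UUCAACG
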