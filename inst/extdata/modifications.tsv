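name	accession
Carbamidomethyl	UNIMOD:4
Oxidation	UNIMOD:35
Acetyl	UNIMOD:1
Phospho	UNIMOD:21
Deamidated	UNIMOD:7
Methyl	UNIMOD:34
Dimethyl	UNIMOD:36
Trimethyl	UNIMOD:37
GlyGly	UNIMOD:121
TMT6plex	UNIMOD:737
TMTpro	UNIMOD:2016
iTRAQ4plex	UNIMOD:214
iTRAQ8plex	UNIMOD:730
Label:13C(6)	UNIMOD:188
Label:13C(6)15N(2)	UNIMOD:259
Label:13C(6)15N(4)	UNIMOD:267
Carbamyl	UNIMOD:5
Gln->pyro-Glu	UNIMOD:28
Glu->pyro-Glu	UNIMOD:27
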