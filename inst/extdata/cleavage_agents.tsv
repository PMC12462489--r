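name	accession	cleavage_site
Trypsin	MS:1001251	(?<=[KR])(?!P)
Trypsin/P	MS:1001313	(?<=[KR])
Lys-C	MS:1001309	(?<=K)(?!P)
Lys-C/P	MS:1001310	(?<=K)
Arg-C	MS:1001303	(?<=R)(?!P)
Asp-N	MS:1001304	(?=[BD])
Chymotrypsin	MS:1001306	(?<=[FYWL])(?!P)
CNBr	MS:1001307	(?<=M)
Glu-C	MS:1001917	(?<=[DE])
PepsinA	MS:1001311	(?<=[FL])
Formic acid	MS:1001308	((?<=D))|((?=D))
2-iodobenzoate	MS:1001318	(?<=W)
proline endopeptidase	MS:1001305	(?<=[HKR]P)(?!P)
unspecific cleavage	MS:1001956	
no cleavage	MS:1001955	
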