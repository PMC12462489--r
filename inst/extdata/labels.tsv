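name	accession
label free sample	MS:1002038
TMT126	MS:1002616
TMT127	MS:1002617
TMT127N	MS:1002763
TMT127C	MS:1002764
TMT128	MS:1002618
TMT128N	MS:1002765
TMT128C	MS:1002766
TMT129	MS:1002619
TMT129N	MS:1002767
TMT129C	MS:1002768
TMT130	MS:1002620
TMT130N	MS:1002769
TMT130C	MS:1002770
TMT131	MS:1002621
TMT131C	MS:1002771
iTRAQ113	MS:1002622
iTRAQ114	MS:1002623
iTRAQ115	MS:1002624
iTRAQ116	MS:1002625
iTRAQ117	MS:1002626
iTRAQ118	MS:1002627
iTRAQ119	MS:1002628
iTRAQ121	MS:1002629
SILAC light	
SILAC medium	
SILAC heavy	
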