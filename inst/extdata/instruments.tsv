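name	accession
Q Exactive	MS:1001911
Q Exactive Plus	MS:1002634
Q Exactive HF	MS:1002523
Q Exactive HF-X	MS:1002877
Orbitrap Fusion	MS:1002416
Orbitrap Fusion Lumos	MS:1002732
Orbitrap Exploris 480	MS:1003028
LTQ Orbitrap	MS:1000449
LTQ Orbitrap Velos	MS:1001742
LTQ Orbitrap Elite	MS:1001910
timsTOF Pro	MS:1003005
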