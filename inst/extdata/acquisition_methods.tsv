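name	accession
data-dependent acquisition	NCIT:C161785
data-independent acquisition	NCIT:C161786
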