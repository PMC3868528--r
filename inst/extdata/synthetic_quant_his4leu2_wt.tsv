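species	percent_signal
IH-dHJ	1.71
IS-dHJ	0.30
CO	19.0
NCO	13.6
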