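species	percent_signal
IH-dHJ	0.44
IS-dHJ	2.00
CO	5.4
NCO	3.0
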