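species	percent_signal
IH-dHJ	0.90
IS-dHJ	0.20
CO	10.0
NCO	10.0
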