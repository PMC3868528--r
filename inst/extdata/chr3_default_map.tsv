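#chromosome=III	centromere_cM=46
name	position_cM
HML	0
CHA1	8
TRP1	21
HIS4	33
CEN3	46
MAT	76
THR4	97
ABP1	114
HMR	131.6
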