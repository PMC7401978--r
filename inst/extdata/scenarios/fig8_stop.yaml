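# miRNA delay experiment, STOP level
model: reduced3
U: 4
S0: 12
A0: 56
B0: 1.5
t_end: 1000
deltaAsigma: 0.18
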