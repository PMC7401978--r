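# Separatrix comparison across the bistable window
model: reduced3
U: [0.0133, 0.133, 4]
S0: 12
A0: 56
B0: 1.5
t_end: 500
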