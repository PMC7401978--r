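# APT initial-condition sweep in the bistable window
model: reduced3
U: 0.1
S0: 12
B0: 1.5
A0: 0
t_end: 2000
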