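# Fate dichotomy, stationary outcome: low UPD from the same initial state
model: reduced3
U: 1
S0: 12
A0: 56
B0: 1.5
t_end: 1000
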