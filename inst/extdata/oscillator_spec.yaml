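# Two coupled oscillators: stiffness block R and gyroscopic coupling T.
R:
- [1.0, 0.0]
- [0.0, 4.0]
T:
- [0.0, -0.5]
- [0.5, 0.0]
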