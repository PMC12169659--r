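6
linear H6 chain, toy fixture (1.0 Angstrom spacing)
H     0.0000000000     0.0000000000     0.0000000000
H     0.0000000000     0.0000000000     1.0000000000
H     0.0000000000     0.0000000000     2.0000000000
H     0.0000000000     0.0000000000     3.0000000000
H     0.0000000000     0.0000000000     4.0000000000
H     0.0000000000     0.0000000000     5.0000000000
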