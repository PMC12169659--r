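2
hydrogen molecule, toy fixture
H     0.0000000000     0.0000000000     0.0000000000
H     0.0000000000     0.0000000000     0.7414000000
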