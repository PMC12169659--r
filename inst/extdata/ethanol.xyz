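9
ethanol (anti), starting structure
C     1.1879000000    -0.3829000000     0.0000000000
C     0.0000000000     0.5526000000     0.0000000000
O    -1.1867000000    -0.2472000000     0.0000000000
H    -1.9237000000     0.3850000000     0.0000000000
H     2.0985000000     0.2306000000     0.0000000000
H     1.1184000000    -1.0093000000     0.8869000000
H     1.1184000000    -1.0093000000    -0.8869000000
H     0.0227000000     1.1812000000     0.8852000000
H     0.0227000000     1.1812000000    -0.8852000000
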