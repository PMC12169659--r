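7
RHF/cc-pVDZ IEF-PCM (eps=78.3553) optimized, E = -95.132151655 Hartree
C      0.0541897399     0.7047209034    -0.0000076046
N      0.0787878030    -0.7453223260     0.0000279856
H     -0.9477503695     1.1380979888    -0.0000129412
H      0.5780147447     1.0796970771     0.8755254845
H      0.5780262451     1.0796637416    -0.8755369552
H     -0.4247712057    -1.0892901444     0.7981789645
H     -0.4246069575    -1.0893572404    -0.7981749335
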