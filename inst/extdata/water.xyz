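3
RHF/cc-pVDZ IEF-PCM (eps=78.3553) optimized, E = -76.036870700 Hartree
O     -0.0000530255    -0.0000328088     0.1164992204
H      0.0000298180     0.7473015408    -0.4687109777
H      0.0000232075    -0.7472687320    -0.4688882427
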