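6
RHF/cc-pVDZ IEF-PCM (eps=78.3553) optimized, E = -114.995802697 Hartree
C     -0.0482034262     0.6530336484    -0.0001086217
O     -0.0436801686    -0.7479900967     0.0003061262
H     -1.0834406840     0.9757688506    -0.0000814296
H      0.4387575296     1.0623192757     0.8834119027
H      0.4387390816     1.0621385041    -0.8836801970
H      0.8553276677    -1.0481601821     0.0001522194
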