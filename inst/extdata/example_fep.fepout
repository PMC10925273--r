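# synthetic NAMD-style FEP output (toy sampler; not an MD trajectory)
#NEW FEP WINDOW: LAMBDA SET TO 0 LAMBDA2 0.05
FepEnergy:      10   -12.0841    -11.9923     3.1102     3.0987     0.2210     0.2210   303.15     0.0000
FepEnergy:      20   -12.1133    -12.0310     3.1240     3.1011     0.1830     0.2020   303.15     0.0000
FepEnergy:      30   -12.0098    -11.9551     3.0889     3.0773     0.1930     0.1990   303.15     0.0000
#NEW FEP WINDOW: LAMBDA SET TO 0.05 LAMBDA2 0.1
FepEnergy:      10   -11.9871    -11.9214     3.0911     3.0855     0.2470   0.2470   303.15     0.0000
FepEnergy:      20   -12.0442    -11.9873     3.1174     3.1040     0.1950   0.2210   303.15     0.0000
FepEnergy:      30   -12.1010    -12.0587     3.1302     3.1177     0.2080   0.2167   303.15     0.0000
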