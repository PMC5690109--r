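# Lead -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM standard grid); L1-L3 and K edges duplicated; M-shell structure (<3.9 keV)
# smoothed; muen between edges approximate (only the muen<=mu bound is relied upon)
# density_default: 11.35 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 5210 5197
1.5 2356 2344
2.0 1285 1274
3.0 1965 1913
4.0 1251 1207
5.0 730.4 699.4
6.0 467.2 444.6
8.0 228.7 213.5
10.0 130.6 119.7
13.035 67.01 59.90
13.035 162.1 128.0
15.0 111.6 91.16
15.200 107.8 87.00
15.200 145.7 115.0
15.861 129.1 101.0
15.861 154.8 120.3
20.0 86.36 68.99
30.0 30.32 25.36
40.0 14.36 12.11
50.0 8.041 6.740
60.0 5.021 4.149
80.0 2.419 1.916
88.005 1.910 1.482
88.005 7.683 2.160
100.0 5.549 1.976
150.0 2.014 1.056
200.0 0.9985 0.5870
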