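# Aluminum -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid); K edge 1.5596 keV duplicated
# density_default: 2.699 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 1185 1183
1.5 402.2 400.1
1.5596 362.1 360.0
1.5596 3957 3829
2.0 2263 2204
3.0 788.0 773.4
4.0 360.5 353.7
5.0 193.4 190.2
6.0 115.3 113.1
8.0 50.33 49.18
10.0 26.23 25.43
15.0 7.955 7.487
20.0 3.441 3.094
30.0 1.128 0.8778
40.0 0.5685 0.3601
50.0 0.3681 0.1840
60.0 0.2778 0.1099
80.0 0.2018 0.05511
100.0 0.1704 0.03794
150.0 0.1378 0.02827
200.0 0.1223 0.02745
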