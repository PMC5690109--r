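# Beryllium -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid)
# density_default: 1.848 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 604.1 603.5
1.5 179.7 179.1
2.0 74.69 74.22
3.0 21.27 20.90
4.0 8.685 8.367
5.0 4.369 4.081
6.0 2.527 2.260
8.0 1.124 0.8839
10.0 0.6466 0.4255
15.0 0.3070 0.1143
20.0 0.2251 0.04780
30.0 0.1792 0.01898
40.0 0.1640 0.01438
50.0 0.1554 0.01401
60.0 0.1493 0.01468
80.0 0.1401 0.01658
100.0 0.1328 0.01836
150.0 0.1190 0.02157
200.0 0.1089 0.02353
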