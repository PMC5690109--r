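# Liquid water -- mass attenuation (with coherent) and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid); see DATA_SOURCES
# density_default: 1.000 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 4078 4065
1.5 1376 1372
2.0 617.3 615.2
3.0 192.9 191.7
4.0 82.78 81.91
5.0 42.58 41.88
6.0 24.64 24.05
8.0 10.37 9.915
10.0 5.329 4.944
15.0 1.673 1.374
20.0 0.8096 0.5503
30.0 0.3756 0.1557
40.0 0.2683 0.06947
50.0 0.2269 0.04223
60.0 0.2059 0.03190
80.0 0.1837 0.02597
100.0 0.1707 0.02546
150.0 0.1505 0.02764
200.0 0.1370 0.02967
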