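# Copper -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM standard grid); K edge 8.979 keV duplicated; muen above 10 keV approximate
# density_default: 8.960 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 10570 10490
1.5 4418 4393
2.0 2154 2142
3.0 748.8 743.0
4.0 347.3 343.8
5.0 189.9 187.0
6.0 115.6 113.2
8.0 52.55 50.54
8.979 38.29 36.52
8.979 278.4 223.0
10.0 215.9 148.4
15.0 74.05 57.00
20.0 33.79 26.70
30.0 10.92 8.780
40.0 4.862 3.900
50.0 2.613 2.080
60.0 1.593 1.246
80.0 0.7630 0.5697
100.0 0.4584 0.3292
150.0 0.2217 0.1271
200.0 0.1559 0.07529
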