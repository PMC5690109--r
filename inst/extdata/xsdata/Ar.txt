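# Argon -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM standard grid); K edge 3.2029 keV duplicated; sub-10 keV rows smoothed
# to a photoelectric power law anchored at the 10 keV value
# density_default: 1.662e-03 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 3184 3170
1.5 1105 1100
2.0 516.1 513.0
3.0 169.7 167.0
3.2029 142.0 140.0
3.2029 1700 1620
4.0 901.0 858.0
5.0 476.0 454.0
6.0 283.0 270.0
8.0 122.8 117.0
10.0 62.66 58.30
15.0 19.57 18.34
20.0 8.630 7.968
30.0 2.697 2.390
40.0 1.228 1.045
50.0 0.7012 0.5741
60.0 0.4664 0.3633
80.0 0.2760 0.1917
100.0 0.2043 0.1259
150.0 0.1427 0.06722
200.0 0.1205 0.04964
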