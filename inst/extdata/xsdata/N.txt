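# Nitrogen -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid)
# density_default: 1.165e-03 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 3311 3306
1.5 1083 1080
2.0 476.9 475.0
3.0 145.6 144.7
4.0 61.66 61.05
5.0 31.44 30.87
6.0 18.09 17.58
8.0 7.562 7.172
10.0 3.879 3.545
15.0 1.236 1.083
20.0 0.6178 0.4601
30.0 0.3066 0.1311
40.0 0.2288 0.05566
50.0 0.1980 0.03217
60.0 0.1817 0.02288
80.0 0.1639 0.01703
100.0 0.1529 0.01617
150.0 0.1353 0.01731
200.0 0.1233 0.01871
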