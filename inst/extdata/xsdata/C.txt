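# Carbon (amorphous) -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid)
# density_default: 2.000 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 2211 2209
1.5 700.2 699.5
2.0 302.6 302.0
3.0 90.33 89.63
4.0 37.78 37.24
5.0 19.12 18.71
6.0 10.95 10.59
8.0 4.576 4.299
10.0 2.373 2.078
15.0 0.8071 0.5627
20.0 0.4420 0.2238
30.0 0.2562 0.06614
40.0 0.2076 0.03343
50.0 0.1871 0.02397
60.0 0.1753 0.02098
80.0 0.1610 0.02037
100.0 0.1514 0.02147
150.0 0.1347 0.02449
200.0 0.1229 0.02655
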