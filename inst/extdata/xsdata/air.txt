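# Dry air (near sea level) -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid); Ar K-edge (3.203 keV) smoothed
# density_default: 0.001205 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 3606 3599
1.5 1191 1188
2.0 527.9 526.2
3.0 162.5 161.4
4.0 77.88 76.36
5.0 40.27 39.31
6.0 23.41 22.70
8.0 9.921 9.446
10.0 5.120 4.742
15.0 1.614 1.334
20.0 0.7779 0.5389
30.0 0.3538 0.1537
40.0 0.2485 0.06833
50.0 0.2080 0.04098
60.0 0.1875 0.03041
80.0 0.1662 0.02407
100.0 0.1541 0.02325
150.0 0.1356 0.02496
200.0 0.1233 0.02672
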