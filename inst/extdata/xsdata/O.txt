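# Oxygen -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid)
# density_default: 1.332e-03 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 4590 4576
1.5 1549 1545
2.0 694.9 693.0
3.0 217.1 215.4
4.0 93.15 92.01
5.0 47.90 47.07
6.0 27.70 27.08
8.0 11.63 11.22
10.0 5.952 5.565
15.0 1.836 1.545
20.0 0.8651 0.6179
30.0 0.3779 0.1729
40.0 0.2585 0.07018
50.0 0.2132 0.03937
60.0 0.1907 0.02745
80.0 0.1678 0.01927
100.0 0.1551 0.01759
150.0 0.1361 0.01824
200.0 0.1237 0.01942
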