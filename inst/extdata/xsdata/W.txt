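# Tungsten -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM standard grid); L1-L3 and K edges duplicated; M-shell structure (<3 keV)
# smoothed; muen above the L edges approximate (only the muen<=mu bound is relied upon)
# density_default: 19.30 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 3683 3671
1.5 1643 1632
2.0 3922 3853
3.0 1573 1500
4.0 956.4 899.6
5.0 558.6 519.3
6.0 354.0 322.2
8.0 170.5 150.9
10.0 96.91 82.93
10.207 91.08 77.84
10.207 223.2 155.0
11.544 160.8 114.8
11.544 231.5 162.4
12.100 203.2 142.9
12.100 238.3 165.0
15.0 139.3 102.9
20.0 65.73 51.30
30.0 22.73 18.09
40.0 10.67 8.428
50.0 5.949 4.590
60.0 3.713 2.751
69.525 2.552 1.818
69.525 11.23 3.250
80.0 7.810 2.879
100.0 4.438 2.131
150.0 1.581 0.9378
200.0 0.7844 0.4000
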