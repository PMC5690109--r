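# Hydrogen -- mass attenuation and mass energy-absorption coefficients
# NIST provenance (XCOM / Hubbell & Seltzer standard grid)
# density_default: 8.375e-05 g/cm^3
# energy_keV mu_over_rho muen_over_rho
1.0 7.217 6.820
1.5 2.148 1.752
2.0 1.059 0.6643
3.0 0.5612 0.1693
4.0 0.4546 0.06549
5.0 0.4193 0.03278
6.0 0.4042 0.01996
8.0 0.3914 0.01160
10.0 0.3854 0.00986
15.0 0.3764 0.01102
20.0 0.3695 0.01355
30.0 0.3570 0.01863
40.0 0.3458 0.02315
50.0 0.3355 0.02709
60.0 0.3260 0.03053
80.0 0.3091 0.03620
100.0 0.2944 0.04063
150.0 0.2651 0.04813
200.0 0.2429 0.05254
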