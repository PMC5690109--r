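# water partial interaction coefficients (cm^2/g)
# Constructed to sum to the bundled total at each grid energy and to make
# analog energy-transfer deposits consistent with muen (photoelectric =
# muen - incoherent x Klein-Nishina mean transfer fraction; incoherent =
# Klein-Nishina x electrons/g x bound-electron suppression; coherent =
# remainder).  See DATA_SOURCES.
# energy_keV photo coherent incoherent
2 615.2 2.07362 0.0264802
3 191.7 1.16066 0.0395675
4 81.9096 0.815676 0.0547449
5 41.8793 0.628701 0.0719887
6 24.049 0.504065 0.0869296
8 9.9133 0.344533 0.112164
10 4.94151 0.254743 0.132748
15 1.36953 0.141563 0.161902
20 0.543895 0.0880349 0.17767
30 0.146033 0.0438063 0.18576
40 0.0570482 0.0255185 0.185733
50 0.0274594 0.0164216 0.183019
60 0.0150787 0.0111566 0.179665
80 0.00581734 0.00581879 0.172064
100 0.00272853 0.00324565 0.164726
150 0.000717088 0.00148561 0.148297
200 0.000273325 0.000839585 0.135887
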