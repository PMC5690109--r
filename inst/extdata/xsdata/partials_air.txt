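# air partial interaction coefficients (cm^2/g)
# Constructed to sum to the bundled total at each grid energy and to make
# analog energy-transfer deposits consistent with muen (photoelectric =
# muen - incoherent x Klein-Nishina mean transfer fraction; incoherent =
# Klein-Nishina x electrons/g x bound-electron suppression; coherent =
# remainder).  See DATA_SOURCES.
# energy_keV photo coherent incoherent
2 526.2 1.67628 0.0238108
3 161.4 1.06463 0.0355788
4 76.3596 1.47115 0.0492262
5 39.3094 0.895888 0.0647317
6 22.6991 0.632728 0.0781664
8 9.44447 0.375669 0.100857
10 4.73976 0.260874 0.119366
15 1.32998 0.138434 0.145581
20 0.533141 0.0849998 0.15976
30 0.145008 0.0417579 0.167034
40 0.0571604 0.0243296 0.16701
50 0.0276984 0.0157324 0.164569
60 0.0152844 0.0106624 0.161553
80 0.00594888 0.0055326 0.154719
100 0.00281004 0.00316976 0.14812
150 0.000751124 0.00150108 0.133348
200 0.000286735 0.000824635 0.122189
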