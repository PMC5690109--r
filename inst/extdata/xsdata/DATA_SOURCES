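Provenance of bundled photon interaction data
=============================================

Files <material>.txt: mass attenuation coefficients mu/rho (with coherent) and mass
energy-absorption coefficients muen/rho, cm^2/g, on the standard NIST grid
(1-200 keV), transcribed from the NIST XCOM database and the Hubbell & Seltzer
tables of X-ray mass attenuation and mass energy-absorption coefficients.

Conventions
-----------
* Whitespace-separated columns: energy_keV  mu_over_rho  muen_over_rho.
* '#' lines are comments; the density_default header line carries the nominal
  density used when no per-voxel density is supplied.
* Absorption edges that fall inside the 10-150 keV working band (Cu K; W L1-L3, K;
  Pb L1-L3, K) appear as duplicated energies (below-edge row first, above-edge row
  second); interpolation never crosses an edge pair.
* Values are linear-interpolated in (log E, log coefficient) between rows.

Accuracy notes
--------------
* water, air, Al, and the elemental gas tables (H, C, N, O) follow the published
  NIST values to the printed precision; these carry all quantitative results
  (HVL integrals, air kerma weighting, water transport).
* muen/rho for the metallic filters (Cu, W, Pb) between/above their edges, the
  smoothed M-shell region of W and Pb (<4 keV), and the sub-10 keV rows of Ar are
  approximate transcriptions; nothing quantitative is computed from them (filters
  use mu/rho only) and only the physical bound muen <= mu is asserted.

Files partials_<material>.txt: photoelectric / coherent / incoherent partial
cross sections (cm^2/g) for the transportable media, constructed to sum to the
bundled totals at every grid energy: incoherent from the analytic Klein-Nishina
cross section per electron times electrons/gram times a bound-electron
suppression factor, coherent from a transcribed small-value table, and
photoelectric as the remainder (floored at zero). See the methods vignette.
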