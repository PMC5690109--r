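# kvbeam

Empirical characterization of a superficial (kilovoltage) radiotherapy X-ray
source, and relative dose computation in voxelized water phantoms under the
kerma approximation.

Superficial X-ray units (40–150 kVp, applicator cones of a few cm at short
SSD) are still commissioned largely from compendium depth-dose tables.
`kvbeam` implements the alternative: characterize the actual machine from
measurements any clinical physics group can make — relative in-air dose
scans at the applicator base and half-value-layer (HVL) transmission series —
and compute patient-independent relative dose (PDDs, profiles) from the
resulting source model.  It is aimed at medical physicists and at method
developers who need a desk-scale, fully scriptable kV dose pipeline.

## The model

The beam is an **effective point source** whose planar fluence at the
applicator plane (z = SSD) is separable,

    phi(x, y, E) = X(x) · Y(y) · U(x, E) · phi0 ,

where `X`, `Y` are relative photon distributions along the inline
(anode–cathode) and crossline axes and `U(x, E)` is the spectrum, varying
only along the inline axis (the heel effect).  Because an in-air chamber
reading is the air-kerma integral

    D_air(x, y) = ∫ phi(x, y, E) (mu_en/rho)_air E dE ,

the fluence is recovered from a relative scan by

    X(x)/X(0) = [D(x,0)/D(0,0)] · ∫U(0,E)(mu_en/rho)_air E dE
                                 / ∫U(x,E)(mu_en/rho)_air E dE .

Spectra are parametric tungsten-anode models (Kramers continuum with target
self-filtration plus the W K lines) whose **inherent filtration is tuned by
bisection until the computed air-kerma HVL matches the measured one**;
measured HVLs come from transmission series via three-point semilogarithmic
interpolation.  Dose is computed by Monte Carlo photon transport
(photoelectric, coherent, incoherent; no electron transport — energy
transferred to electrons is deposited locally) through a voxel phantom, with
a deterministic primary-kerma component and a point-detector scatter
estimator at each point of interest.

## Worked example

```r
library(kvbeam)

# 120 kVp beam, 0.05 mm Cu + 0.90 mm Al added filtration (nominal tube data)
sp <- generate_spectrum(120, added = filter_stack(Cu = 0.05, Al = 0.90))
air_kerma_hvl(sp)
#> [1] 3.971996

# tune the inherent filtration to the measured HVL of 4.18 mm Al
fit <- tune_inherent_filtration(120, added = filter_stack(Cu = 0.05, Al = 0.90),
                                target_hvl_mm_al = 4.18)
fit$thickness_mm_al; fit$hvl
#> [1] 0.2734375
#> [1] 4.184566

# flat 5 cm applicator source at SSD 15 cm, dose on the central axis
pos <- seq(-2.5, 2.5, by = 0.5)
scan <- function(ax) inair_scan(ax, pos, rep(1, length(pos)), 5, 15)
src <- build_source(120, 15, 5, scan("inline"), scan("crossline"),
                    spectrum_set(0, list(fit$spectrum)))
ph  <- build_water_phantom(surface_z = 15)
d   <- compute_dose(src, ph, data.frame(x = 0, y = 0, z = 15 + 1:10),
                    n_histories = 2e5, seed = 1)
extract_pdd(d, ssd_cm = 15)
#>    depth_cm       pdd     stderr
#> 1         1 75.899506 0.32115443
#> 2         2 57.361018 0.26989854
#> 3         3 43.415693 0.24613741
#> ...
#> 10       10  6.794860 0.09586244
```

The first HVL printed for the nominal beam (3.97 mm Al) is within 5% of the
measured 4.18 mm Al; after tuning, the spectrum reproduces it to 0.01 mm.
The PDD is normalized to 100 at the surface (polynomial extrapolation of the
shallow points, the kV convention) and falls to a few percent by 10 cm depth,
as expected for a 4.2 mm Al beam on a 5 cm cone at SSD 15 cm.

A command-line driver over the same functions is installed at
`inst/cli/kvbeam` (subcommands `spectrum`, `hvl`, `characterize`, `phantom`,
`dose`, `pdd`, `profile`, `compare`, `fixtures`, `run`).

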