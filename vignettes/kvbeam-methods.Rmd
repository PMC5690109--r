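---
title: "kvbeam: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kvbeam: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the known
limitations.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The source model

A superficial therapy beam is modeled as an effective point source at the
focal-spot position.  Everything the phantom sees is encoded in the planar
fluence at the applicator base (z = SSD), assumed separable:

$$\phi(x, y, E) = X(x)\, Y(y)\, U(x, E)\, \phi_0 .$$

`x` is the inline (anode–cathode) axis, the only direction along which the
spectrum varies — the heel effect both depresses the fluence and hardens the
spectrum toward the anode side.  `y` is crossline.  $\phi_0$ is a
calibration constant; it is fixed at 1 because the package computes relative
dose only, and is retained in the type for forward compatibility with
absolute calibration.

**Fluence recovery.**  An in-air ionization chamber reads air kerma,
$D_{air}(x,y) = \int \phi\, (\mu_{en}/\rho)_{air}\, E\, dE$, so a relative
scan divided by the spectral kerma ratio yields the fluence:

$$\frac{X(x)}{X(0)} = \frac{D_{air}(x,0)}{D_{air}(0,0)}
  \cdot \frac{\int U(0,E)(\mu_{en}/\rho)_{air} E\, dE}
             {\int U(x,E)(\mu_{en}/\rho)_{air} E\, dE}.$$

`fluence_from_inair()` implements this; when all stations share one spectrum
the correction cancels and the fluence *is* the normalized scan (asserted
exactly in the tests).  The forward map `inair_dose_at()` and this inverse
are mutual inverses to < 1e-6 at the sample points (round-trip test).

**Interpolation and penumbra.**  Fluence is linear between scan samples.
Beyond the outermost sample it falls linearly to zero over one sample
spacing.  This tail is a documented knob, not a measurement: edge
measurements on real units deviate by up to ~10%, and no tail shape is
derivable from scans that stop at the aperture edge.  Emission sampling is
restricted to the aperture disk; the tail matters only to the forward model
near the field edge.

**Spectrum stations** are assigned nearest-neighbor in x, matching the 3 cm
granularity at which off-axis HVLs are measured.  Linear interpolation
*between spectra* is deliberately not offered: it is not defined by any
measurement the pipeline takes.

## 2. Spectra and HVL

`generate_spectrum()` is a parametric tungsten-anode model:

* **Continuum**: Kramers photon-number spectrum $N(E) \propto E_{max}/E - 1$
  in 0.5 keV bins (HVLs move by < 0.01 mm under bin halving; the
  `kerma_integral` refinement test quantifies this).
* **Target self-filtration**: the continuum is attenuated through tungsten
  along the anode exit path $s = d/\sin\theta$, with mean production depth
  $d = V^2 / (2\rho_W C_{TW})$ from a Thomson–Whiddington range.
  $C_{TW} = 1.2\times10^6\ \mathrm{keV^2\,cm^2/g}$, at the upper end of the
  literature range; this choice also leaves the untuned spectra slightly
  *soft*, so that HVL matching (which can only add inherent filtration) has
  room to work at most beam qualities.
* **Characteristic lines**: the four W K lines (57.98, 59.32, 67.24,
  69.07 keV) at intensity ratios 58 : 100 : 33 : 9, total fluence scaled as
  $(V/E_K - 1)^{1.67}$ with one amplitude constant (0.08) fixed so the
  K-line fluence share is ~10% at 150 kVp before added filtration,
  consistent with published tungsten spectra.

**HVL is defined on air kerma**, not photon number: the transmission
integral is weighted by $(\mu_{en}/\rho)_{air} E$, because an
ionization-chamber HVL measurement responds to kerma.  `air_kerma_hvl()`
solves transmission = 1/2 by bracketed root finding to |T − 0.5| < 1e-6.
Whether third-party spectrum tools define HVL on kerma or exposure is not
documented in the sources this package follows; kerma was chosen and is used
consistently everywhere.

**Tuning** (`tune_inherent_filtration()`) treats the inherent filtration as
a single unknown Al-equivalent thickness in [0, 20] mm and bisects on it —
HVL is strictly monotone in added filtration, so convergence is guaranteed —
to |HVL − target| < 0.01 mm.  The nominal Be window is absorbed into the
Al-equivalent parametrization; a target below the zero-inherent floor of the
family is reported as unreachable together with the achievable bracket.
This floor is a real limitation: the measured 140 kVp quality
(7.14 mm Al behind 0.20 mm Cu + 1.15 mm Al) lies *below* what any spectrum
in this Kramers family can produce with that added filtration (~7.9 mm Al
even with no inherent filtration and no K lines).  Empirical continuum
models are softer at high tube potential than a self-filtered Kramers shape;
reproducing that quality requires the `import_spectrum()` hook with an
externally generated spectrum.  The acceptance suite keeps the 140 kVp HVL
assertion at its stated tolerance and it fails honestly (+12%); the 120 and
150 kVp qualities reproduce within 10% from nominal tube data alone.

**Three-point HVL** (`hvl_three_point()`) fits a quadratic in
(thickness, log transmission) through the three measured points nearest 50%
transmission and returns the in-bracket root.  This is exact for
monoenergetic beams and second-order accurate for hardened beams; on
forward-modeled data it agrees with the spectral HVL to < 0.05 mm for
brackets within ±30% of the true value — well inside the ±0.1 mm (central)
to ±0.3 mm (off-axis) repeatability of the measurements it replaces.  The
nearest-three selection (rather than two-below/one-above) was chosen and
documented; the alternative is selectable by flag.

## 3. Interaction data

Mass attenuation and mass energy-absorption coefficients for water, air, Al,
Cu, Be, W, Pb and the air elements ship as plain-text tables of NIST
provenance (`inst/extdata/xsdata/`, see `DATA_SOURCES`).  Interpolation is
linear in (log E, log coefficient) — standard for photon cross sections and
near-exact between grid knots; absorption edges in band (Cu K; W and Pb
L, K) are stored as duplicated energies so interpolation never crosses an
edge.  Compounds use the mass-fraction mixture rule; the bundled air table
and air rebuilt from its elements agree within 2% across 10–150 keV (tested).

The transport engine additionally needs the photoelectric / coherent /
incoherent split.  The bundled partials are *constructed*, not transcribed:
incoherent is the analytic Klein–Nishina cross section per electron times
electrons/gram times a bound-electron suppression factor; photoelectric is
set to $\mu_{en} - \mu_{inc}\,\bar f_{tr}(E)$ (with $\bar f_{tr}$ the KN
mean electron-energy fraction), which makes analog energy-transfer deposits
consistent with the tabulated $\mu_{en}$ by construction; coherent is the
remainder against the tabulated total.  The package's three scoring routes
(below) cross-check this construction.

## 4. Transport and scoring

Photons are transported through the voxel grid with an incremental
Siddon-style walk; free paths are sampled by accumulating optical depth
$-\ln\xi$ across voxels (chord bookkeeping is exact to 1e-9, tested).
Physics: photoelectric absorption (full local deposit), incoherent
scattering (Kahn-sampled Klein–Nishina energy/angle, Compton kinematics,
electron share deposited locally — the kerma approximation), coherent
scattering (Thomson-shaped $1 + \cos^2\theta$ angle, no energy loss).
Electron transport is deliberately absent: kV secondary-electron ranges are
below the tally resolution.  Atomic form factors for coherent scattering are
not applied (the Thomson shape is used); coherent scattering can be disabled
by flag, and its effect on relative PDD in water at these energies is small.
Photons falling below the 5 keV cutoff are absorbed on the spot (sub-5 keV
photons have sub-millimeter range in water, below tally resolution); this
local-deposit termination keeps the per-history energy ledger exact, which a
roulette scheme would only preserve in expectation.

`compute_dose()` offers three scoring routes:

* **`kerma`** (default): the uncollided primary kerma at each POI is
  computed deterministically — for a point source the primary fluence at a
  point comes from the single ray through it, so the component is an exact
  1D spectrum quadrature attenuated along the traced voxel path — and the
  scatter kerma is estimated by a next-event (point-detector) contribution
  from every scattering event, $w\,p(\Omega)\,e^{-\tau}/r^2\,
  (\mu_{en}/\rho)(E')\,E'$.  Within `nee_rmin` (default 0.5 cm) of a
  detector the $1/r^2$ kernel is replaced by its bounded sphere average
  $3(1 - e^{-\mu R})/(\mu R^3)$.  This route makes point-of-interest dose
  converge at the history counts used in practice.
* **`collision`**: analog deposits in tally boxes, with an exact per-history
  ledger (deposited + escaped = launched; the maximum imbalance is reported
  and tested at the 1e-9 level).
* **`tracklength`**: chord-length fluence scoring through the tally boxes
  times $(\mu_{en}/\rho)E$.

The three routes are independent estimators of the same quantity and agree
within statistics on the water-phantom POIs (tested); `kerma` is used for
all PDD/profile production, `collision` for conservation properties,
`primary` (first-interaction termination) for Beer–Lambert checks.

Randomness: emission sampling uses R's RNG under `set.seed(seed)`;
the C++ transport uses xoshiro256++ seeded by splitmix64 from the same seed.
Identical inputs and seed give bit-identical results (tested).

Tallies are voxel boxes (default 0.4 × 0.4 × 0.3 cm³) centered on the
requested POIs; "point" dose is the box value — finite-volume scoring is
intrinsic to MC, and the box is small against every field size used.

## 5. Phantoms

`build_water_phantom()` creates homogeneous water grids; the
measurement-scale reference grid is 512 × 512 × 108 voxels of
0.081 × 0.081 × 0.30 cm³ (28,311,552 voxels; its stated 41.2 cm transverse
extent and 512 × 0.081 = 41.47 cm are mutually inconsistent in the source
description — both constructions are supported and the discrepancy is noted,
not resolved).  The default dose-engine grid downsamples the transverse
plane to 103 × 103 × 0.4 cm voxels (41.2 cm), which POI tallies do not
resolve beyond.  HU volumes map to material + density through ordered
interval ramps (`hu_mapping()`); the native volume format is raw
little-endian arrays (z-fastest) with a JSON sidecar, chosen over DICOM so
that phantoms are diffable, seekable and testable without imaging fixtures.
Voxel indexing is 0-based in the file format and engine; world coordinates
are voxel-center based; the phantom surface plane sits at z = SSD.

## 6. Synthetic measurements

The fixtures module stands in for the physical machine.  `make_heel_source()`
builds a truth source with a linear inline HVL gradient (each station's
spectrum tuned to `hvl_center + gradient·x`), an inline fluence reduced
linearly by 10% toward the anode side, and a flat-topped crossline profile
whose cosine edges drop 10% at the rim — the magnitudes reported for real
applicators.  Its defaults (120 kVp behind 1 mm Al, central HVL 4.5 mm Al,
15 cm applicator at SSD 25) are chosen so the station targets sit well
inside the tunable range.  `synthetic_inair_scan()` and
`synthetic_transmission()` sample the truth forward models with
multiplicative Gaussian reading noise, default SD 0.3% — the stated
chamber reading uncertainty; only the magnitude is stated anywhere, so the
distribution shape is this package's documented choice.  All generators take
explicit seeds and record them.

What the fixtures do *not* emulate: chamber energy response and
volume averaging, setup (positioning) error, scatter into the HVL geometry,
applicator-wall scatter, and focal-spot blur (the source is a point; the
real focal spot is 7.5 mm).  Passing the recovery tests therefore
demonstrates that the *inversion machinery* is unbiased at realistic reading
noise — not that those physical effects are negligible on a real unit.

## 7. Problem sizes and test design

The test and acceptance runs use desk-scale sizes chosen as the package's
own defaults: unit-test MC runs use 2×10³–4×10⁵ histories; the PDD
monotonicity/ordering checks use 10⁵ histories per beam on the
103 × 103 × 108 water grid; the convergence comparison uses the 5×10⁵ and
10⁶ histories that define it; the matched-HVL PDD equivalence uses 4.5×10⁶
histories per spectrum so every per-point standard error is below 0.3%.
Statistical assertions use 3–3.5 standard errors or χ²/KS p > 0.01 at fixed
seeds.

## 8. Known limitations

* The parametric spectrum family cannot reach very soft high-kVp qualities
  (the 140 kVp case above); external spectra can be imported instead.
* Coherent scattering lacks form factors; below ~20 keV its angular
  distribution is therefore too backward-peaked.  Irrelevant for relative
  water PDDs here, wrong if the engine were pointed at angular-resolved
  coherent observables.
* No electron transport, bremsstrahlung, or fluorescence tracking: valid
  for water/air at ≤ 150 kVp, not for high-Z media or interface dosimetry.
* `muen` values bundled for the metallic filters between their edges are
  approximate (filters only ever use total attenuation; see DATA_SOURCES).
* Absolute dose (phi0, TG-61 formalism, backscatter/chamber factors) is out
  of scope; every output is relative.
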