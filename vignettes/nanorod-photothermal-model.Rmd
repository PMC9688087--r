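---
title: "Modeling nanorod-mediated photothermal therapy with nanotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nanorod-mediated photothermal therapy with nanotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotherm)
```

# The problem

Laser interstitial thermal therapy destroys focal tumors by heating them
with near-infrared light delivered through a thin fiber. Plain tissue is
only weakly absorbing at 808 nm, so the heating is diffuse and poorly
selective. Gold nanorods (GNRs) tuned so that their longitudinal surface
plasmon resonance sits at the laser wavelength absorb light orders of
magnitude more strongly per unit volume; infusing a tumor with a dilute
rod suspension concentrates the deposited energy in the target.
`nanotherm` simulates this treatment on synthetic voxel phantoms: a
cubic pancreas block with an embedded spherical tumor for the
interstitial scenario, and a thin water drop in a multiwell plate for a
surface-illumination benchmark.

The pipeline has four stages, each exposed as ordinary functions and
bundled by `run_scenario()`:

1. **Nanorod optics** — absorption cross section of a single rod and
   the bulk nano-absorption coefficient of the loaded tissue.
2. **Monte Carlo photon transport** — analog random walk of optical
   photons through the voxel grid, scoring deposited energy.
3. **Heat conversion** — deposited eV per voxel to temperature rise.
4. **Bioheat diffusion** — analytic Green's-function evolution of the
   temperature field, with virtual probes and plane maps.

# Nanorod optics

A rod of diameter $D$ and length $\ell$ is treated as a prolate
spheroid in the quasi-static (Gans) approximation. The depolarization
factor of the long axis is

$$P_1 = \frac{1-x^2}{x^2}\left[\frac{1}{2x}\ln\frac{1+x}{1-x} - 1\right],
\qquad x = \sqrt{1-(D/\ell)^2},$$

with $P_2 = P_3 = (1-P_1)/2$; at $D=\ell$ the continuous extension
$P_i = 1/3$ recovers the sphere. The axis polarizabilities are

$$\alpha_i = 4\pi abc\,
\frac{\varepsilon-\varepsilon_m}{3\varepsilon_m + 3P_i(\varepsilon-\varepsilon_m)},$$

with semi-axes $a=\ell/2$, $b=c=D/2$, particle permittivity
$\varepsilon$ and host permittivity $\varepsilon_m$, and the
orientation-averaged absorption cross section is
$C_\mathrm{abs} = k\,\mathrm{Im}\,\langle\alpha\rangle$ with
$k = 2\pi\sqrt{\varepsilon_m}/\lambda$. This convention reduces exactly
to the Clausius–Mossotti small-sphere polarizability and agrees with
the dipole term of Mie theory to better than 1% for 5 nm spheres (both
are asserted in the test suite).

Metal permittivity comes from a packaged Johnson–Christy-type
dispersion table, interpolated linearly in wavelength, plus a finite-size
correction: the difference of two Drude terms in which the bulk damping
$\gamma_b = v_F/\ell_{mfp}$ (Fermi velocity over the 42 nm electron mean
free path of gold) is replaced by
$\gamma_a = \gamma_b + g\,v_F/a_{eq}$, with surface-scattering constant
$g = 1$ and $a_{eq}$ the volume-equivalent radius of the rod modeled as
an *s-cylinder* (a cylinder with hemispherical caps). The correction
only adds loss; it raises the imaginary part of the gold permittivity at
808 nm by roughly a factor of two for a $10\times41$ nm rod, which is
what makes the small-particle cross section finite and realistic.

For a mass concentration $c$ of rods (µg/mL) the volume fraction is
$c/\rho_{Au}$ with bulk gold density 19.3 g/cm³, the number density is
$N = $ fraction / rod volume, and the nano-absorption coefficient of
the loaded tissue is $\mu_a^{nano} = N\,C_\mathrm{abs}$, with
nano-absorption length $L_a = 1/\mu_a^{nano}$.

Two permittivity inconsistencies in the source data are worth knowing
about. The packaged tissue table lists the pancreas host permittivity
as 1.767, which is the square of water's refractive index, not of the
pancreas' own RI 1.394 ($1.394^2 = 1.943$); the packaged nanorod-loaded
row stores the particle permittivity $-24.718 + 3.6581i$. With the
listed host (1.767) the Gans resonance of the 4.1 aspect-ratio rod
falls some tens of nm short of 808 nm with our dispersion table; with
the tissue host ($1.943$) it falls within 20 nm of 808 nm (asserted in
the test suite). The default scenario uses
the listed values, because they reproduce the published cross section;
the resonance-location sanity test uses the tissue host. Both are plain
arguments to `absorption_cross_section()` and `cross_section_spectrum()`.

# Photon transport

Transport is analog: each photon carries the full beam energy
$E_0 = hc/\lambda$ (1.5345 eV at 808 nm) and is absorbed whole. Free
paths are sampled from the current voxel's total attenuation
$\mu_t = \mu_a + \mu_a^{nano} + \mu_s$ with optical-depth tracking
across voxel boundaries, so piecewise-homogeneous media are handled
exactly. At an interaction, the channel (tissue absorption, nanorod
absorption, scattering) is chosen in proportion to its coefficient.
Scattering deflects the photon by a Henyey–Greenstein angle; the
packaged tissue table carries no measured anisotropy, so the package
defaults to $g = 0.9$, a typical NIR soft-tissue value, and $g = 0$
for water. The
world boundary absorbs (photons escape). Refractive-index mismatch at
internal boundaries is not modeled; the inclusions are index-matched to
the bulk.

The core loop is compiled (Rcpp) with a dedicated xoshiro256++
generator seeded from the run seed, so identical seeds give
bit-identical energy maps regardless of R's RNG state. Per-voxel
absorption counts $N_p$ accompany the energy map; the per-voxel
relative statistical uncertainty follows the printed estimator
$1/\sqrt{N_p(N_p-1)}$. Note that this estimator scales like $1/N_p$,
i.e. linearly in the history count; the familiar $1/\sqrt{n}$ Monte
Carlo scaling applies to the Poisson relative error $1/\sqrt{N_p}$,
which is what the scaling property test measures.

Validation oracles: a pure absorber reproduces Beer–Lambert attenuation
(fitted coefficient within 2% at $10^6$ histories); splitting one
absorption coefficient into tissue + nano channels leaves the depth
profile unchanged; photon and energy bookkeeping are exact.

# Heat conversion

Two conversions are implemented.

*Calorimetric*: a voxel of mass $m$ and heat capacity $C_p$ warms by
$F = 1.602\times10^{-19}/(m\,C_p)$ °C per deposited eV.

*Per-voxel nanoparticle term*: the quasi-steady excess temperature of a
uniformly heated rod-loaded region of radius $R$ (the voxel half-size)
under irradiance $I$, $\Delta T = N R^2 C_\mathrm{abs} I/(2k)$, with
the voxel irradiance $I = E[\mathrm{eV}] \cdot 1.602\times10^{-19} /
(t_{laser}\,A_{voxel})$.

Whether the nanoparticle term should *replace* or *supplement* the
calorimetric conversion in loaded voxels is genuinely open in the
source material. The package default (`heat_model = "auto"`) adds it on
top of the calorimetric term. The reason is physical: per deposited eV
the nanoparticle term is almost three orders of magnitude smaller than
the calorimetric factor (it describes a single voxel's steady
conduction halo, not the energy balance), so using it *instead* would
make a nanorod-loaded tumor compute as colder than the same tumor
without rods — contradicting both the physics and the qualitative
behavior the simulator exists to reproduce. `heat_model = "tissue"` and
`"gnr"` force either pure path.

The simulated emission rate (2×10⁶ photons/s) is far below the physical
photon rate of a watt-class laser, so converted maps are multiplied by
a *photon-flux scaling factor*, flux / emission rate. The flux
convention is configurable (`area_unit`): the default `"mm2"` evaluates
the beam cross-section in mm², reproducing the published worked example
(≈1.2×10²⁰ photons/s per area unit and a scaling factor ≈6×10¹³ for
2.1 W through a 0.3 mm tip), and makes the scaling scale as $1/d^2$
with tip diameter. Be aware that this convention is *not* energy
conserving: scaling × emission rate × $E_0$ × beam area equals the beam
power, so using the per-area flux as a per-photon multiplier overcounts
the injected power by the numeric beam area (≈14× for 0.3 mm). The
`"photon"` convention uses the photon-count ratio $P/(E_0\,\mathrm{Bq})$,
which conserves energy exactly but is independent of the tip diameter.
Absolute temperatures therefore differ by an order of magnitude between
the conventions; relative statements (orderings in power, diameter, and
nanorod loading) are unaffected. The packaged scenarios follow the
published convention (`"mm2"`).

# Bioheat diffusion

With constant coefficients and no source, the Pennes equation has the
Green's-function solution: convolution with a normalized Gaussian of
per-axis width $\sigma = \sqrt{2\alpha t}$, times the perfusion decay
$e^{-Q_b t}$. `diffuse()` evaluates the convolution spectrally on a
zero-padded grid (padding ≥ 4σ) with the analytic transfer function
$e^{-\alpha t |\omega|^2}$, which is exactly mass-conserving and agrees
with an explicit finite-difference solver to within 2% in the maximum
norm (asserted in the tests). The solver uses a single diffusivity per
run: 0.16 mm²/s for the nanorod-loaded tumor scenarios (a measured
mixture value), 0.14 mm²/s for plain pancreas, 0.143 mm²/s for water.
Perfusion defaults to zero, matching the ex vivo and phantom
benchmarks; setting `wb` (with blood density/heat capacity) on a
material enables it.

Continuous-wave heating is approximated by superposition: the
per-second physical heating map is injected at sub-interval boundaries
(default Δt = 1 s) and each injection diffuses for its remaining time.
Because Gaussian kernels compose ($\sigma^2$ adds), the implementation
steps once per Δt in the Fourier domain and transforms back only at
requested output times; the result is independent of how the interval
is subdivided up to the injection discretization, and halving Δt moves
a 2 mm probe at 120 s by well under 2% (asserted). `probe_curve()`
computes the same superposition directly at a single point for dense
time series without field-sized transforms.

Baseline temperature defaults to 26 °C (the benchmark room/ambient
condition). Temperature-dependent properties, vaporization and
carbonization are not modeled; outputs above a working threshold
(default 155 °C absolute) are outside the model's validity, and
`apply_threshold()` truncates probe series at the first exceedance
accordingly.

# The packaged scenarios

`scenario_pancreas_ptt()` builds the interstitial scenario: a 4 cm³
cubic pancreas world ("4 cm³" is read as a volume, edge
$4^{1/3}$ cm ≈ 15.9 mm) at 0.25 mm voxel pitch (the "0.25 mm cubes"
read as edge length), with a 3 cm³ spherical tumor centered on the
fiber tip at the origin. A 3 cm³ sphere (radius 8.95 mm) does not quite
fit the cube (half-edge 7.94 mm), so the packaged tumor is truncated at
the world faces; `embed_spherical_tumor()` errors on an oversized
sphere unless `clip = TRUE`. Rods are 10×41 nm at 12.5 µg/mL, uniformly
distributed in the tumor; the nano-absorption coefficient defaults to
the computed $N\,C_\mathrm{abs}$ (`nano_mu_a = "table"` forces the
published tabulated value instead — the two disagree, one of several
internal inconsistencies in the source parameters). The source is an
808 nm collimated disc of 0.3 or 0.6 mm diameter emitting 2×10⁶
simulated photons/s along +z for up to 120 s at 1.2 or 2.1 W. Virtual
probes sit 2 mm lateral (hd) and 2 mm along-beam (vd) from the tip.

`scenario_water_drop()` models the surface benchmark: a 0.1 mL drop as
a cylinder of radius 7.75 mm (a 24-well footprint, so the drop is only
≈0.5 mm deep) of water, plain or with 0.625 mg/mL rods, in air,
illuminated from above for 30 s through a 3 mm collimated beam (the
collimator aperture is not specified in the source; 3 mm is a typical
collimated spot and is configurable). The reported quantity is the
maximum surface temperature rise, mirroring an IR camera.

What the synthetic phantoms do *not* emulate: anatomical organ shape
(the tumor is a sphere, not a segmented pancreas head), heterogeneous
rod distribution, refractive-index boundaries, blood perfusion in vivo,
and any temperature dependence of tissue properties. Passing tests on
these phantoms validates the numerics and the parameter chain, not
clinical realism.

# Numerical choices and degenerate inputs

* Geometry: 0-based voxel indices internally, world coordinates at
  voxel centers, world box centered on the origin; label volumes always
  sum exactly to the world volume.
* Transport: optical depth is conserved across boundary crossings; a
  1 nm nudge prevents voxel-edge stalls; transparent voxels (air) are
  traversed ballistically; `max_steps` (default 10⁶) guards against
  pathological loops and terminated photons are counted and reported.
* Diffusion at $t = 0$ returns the field unchanged; a zero-diffusivity
  model only applies the perfusion factor; kernels with σ below the
  pitch are handled by the spectral form (no sampled-kernel
  normalization error).
* Cross sections: the resonance denominator $3\varepsilon_m +
  3P_i(\varepsilon-\varepsilon_m)$ raises a singularity error if it is
  exactly zero; absorptive hosts (complex $\varepsilon_m$) are rejected
  as unsupported rather than silently mis-normalized.
* Material tables are validated row by row; element compositions are
  normalized to unit sum at load time (the published table sums to ≈10,
  read as ×10 percent).

# Known limitations

* Analog capture only (no implicit weighting), so deep-tissue tails are
  noisy at small history counts.
* The quasi-static rod optics ignores retardation, multipoles and
  inter-particle coupling; it underestimates the resonance redshift of
  real rods by a few tens of nm depending on the host.
* Single-diffusivity bioheat: no heterogeneous conduction across the
  tumor boundary.
* The published parameter set is internally inconsistent (flux-scaling
  area convention, tabulated vs computed nano-absorption, host
  permittivity); the package exposes each choice as configuration and
  documents the defaults rather than silently reconciling them.
  Absolute temperatures inherit those choices and should be read
  comparatively.
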