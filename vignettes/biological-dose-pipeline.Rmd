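---
title: "From track structure to voxelized biological dose: the methods behind hadrondose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From track structure to voxelized biological dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadrondose)
```

# The problem

Carbon-ion therapy beams are not biologically equivalent to photon beams:
the dense ionization around an ion track kills cells far more efficiently
per gray, and the efficiency changes along the beam path as the ions slow
down. Treatment evaluation therefore needs, per voxel, not only the
physical dose D but the *biological dose* — the photon dose that would
produce the same cell-survival effect — and their ratio, the relative
biological effectiveness (RBE). `hadrondose` implements that chain for a
mixed radiation field: a microdosimetric engine that predicts
linear-quadratic (LQ) survival coefficients for monoenergetic ions, a
coefficient-database layer, a voxelized accumulator that mixes
coefficients over the local particle spectrum, and a spread-out Bragg
peak (SOBP) builder, together with a synthetic one-dimensional beam
generator that makes the whole pipeline testable without a Monte Carlo
transport code.

# Cell survival and the mMKM

Survival after a uniform dose D follows the LQ model
$S(D) = e^{-\alpha D - \beta D^2}$. The modified microdosimetric kinetic
model (mMKM) predicts the ion- and energy-dependence of $\alpha$ from the
stochastics of energy deposition in micrometre-scale subnuclear *domains*:

$$\alpha = \alpha_0 + \beta\, z_{1D}^*,$$

where $z_{1D}^*$ is the *saturation-corrected dose-mean specific energy*
of a single deposition event in the domain,

$$z_{1D}^* = z_0^2\,
  \frac{\int_0^\infty \bigl(1 - e^{-z^2/z_0^2}\bigr) f_1(z)\,dz}
       {\int_0^\infty z\, f_1(z)\,dz},
\qquad
 z_0 = \frac{(R_n/R_d)^2}{\sqrt{\beta\,\bigl(1 + (R_n/R_d)^2\bigr)}}.$$

$f_1(z)$ is the single-event density of specific energy z in the domain.
The saturation parameter $z_0$ caps the contribution of very large z and
reproduces the *over-killing* turnover: beyond roughly 100–150 keV/µm,
extra local energy is wasted on already-dead cells and $\alpha$ stops
growing. The default parameters are the reference HSG (human salivary
gland tumor) cell-line set: domain radius $R_d = 0.32$ µm, nucleus radius
$R_n = 3.9$ µm, $\alpha_0 = 0.172$ Gy$^{-1}$, $\beta = 0.0615$ Gy$^{-2}$,
giving $z_0 \approx 48.98$ Gy. $\beta$ is treated as LET-independent, as
the affine $\alpha$ relation implies.

The NanOx model enters this package only through its published HSG
parameter set and the effective local-lethal function
$F(z) = \tfrac{h}{2}(1 + \mathrm{erf}((z - z_0^{nx})/\sigma))$
(`nanox_lethal_function()`); the full NanOx survival computation requires
nanometric Monte Carlo track-structure spectra and is out of scope. Where
a NanOx coefficient database is needed for pipeline exercises,
`build_synthetic_nanox_table()` generates a clearly labelled synthetic
stand-in (mMKM values with a saturating high-LET enhancement). The
numerals of the published NanOx threshold and maximum are read as
thousands-separated integers (15654 Gy, 179439); the decimal-comma
reading is physically implausible for 10 nm targets but remains available
through `nanox_params()` arguments.

# Amorphous-track microdosimetry

$f_1(z)$ is computed from the Kiefer–Chatterjee (KC) amorphous-track
picture rather than from event-by-event track-structure simulation: the
average radial dose around an ion path is a constant-dose core of radius
$r_c = 0.0116\,\beta_v$ µm ($\beta_v$ = ion speed / c) surrounded by a
$1/r^2$ penumbra out to $r_p = 0.0616\,E^{1.7}$ µm (E in MeV/n). The
penumbra coefficient is $1.25\times10^{-4} (Z_{\mathrm{eff}}/\beta_v)^2$
Gy µm² and the core dose is normalized so the radial integral reproduces
the ion's unrestricted LET in water — so LET closure holds by
construction and is verified to 2% by quadrature in the tests. The
effective charge follows the continuous Barkas rule
$Z_{\mathrm{eff}} = Z(1 - e^{-125\beta_v Z^{-2/3}})$; a continuous rule
avoids the spurious discontinuities in $z_{1D}^*$ that a coarsely
quantized effective charge produces. LET itself is taken from a bundled
water stopping-power table per ion (Bethe formula with the same Barkas
charge, 0.05–500 MeV/n), interpolated log-log.

The specific energy deposited in a domain whose axis passes at impact
parameter b from the track is the area-average of the radial dose over
the domain cross-section, $z(b)$, computed by piecewise quadrature over
the chord-overlap geometry. For a uniform fluence, impact parameters
carry the measure $2\pi b\,db$ on $[0, R_d + r_p]$, which maps through
$z(b)$ into $f_1(z)$.

Numerical choices that matter:

* **Impact-parameter grid.** $z(b)$ spans many decades between the track
  core and the penumbra edge, and for slow ions the entire track fits
  inside the domain, making z(b) flat except in a narrow annulus
  $|b - R_d| < r_p$. The grid is therefore log-spaced in b with explicit
  extra nodes across that annulus; a uniform-in-$b^2$ grid (the naive
  "equal geometric weight" choice) puts essentially all of its cells
  outside the structure and misestimates the frequency mean several-fold.
* **Self-checks.** The frequency mean has a closed geometric form,
  $\bar z = \mathrm{LET}\cdot k / (\pi b_{max}^2)$ (Fubini), which the
  quadrature must reproduce (tested at 0.2%); moments are also checked
  against a Monte Carlo impact-parameter sampler (10^6 draws, 3
  standard-error agreement).
* **Density representation.** $f_1$ is stored as a histogram on the z
  bins induced by the b cells, so $\int f_1\,dz = 1$ holds to machine
  precision by telescoping, and $z_{1D}^* \le z_{1D}$ is an exact
  algebraic consequence of $1 - e^{-x^2} \le x^2$ on the same measure.
* **Default resolution** is 2048 impact-parameter nodes and 97 radial
  nodes per quadrature segment; coefficient tables in the test suite use
  768–1024 nodes, which keeps every tabulated $\alpha$ within a fraction
  of a percent of the high-resolution value.

One consequence of the physics worth stating explicitly: $\alpha \to
\alpha_0$ as LET $\to 0$ holds for every ion *as a limit*, but only
hydrogen actually reaches the low-LET regime inside the supported
0.1–400 MeV/n window. Minimum-ionizing carbon still deposits
~11 keV/µm, so its $\alpha$ floor (~0.34 Gy$^{-1}$) sits well above
$\alpha_0$ — as it does in published mMKM databases. The test suite
asserts the limit exactly, the monotone approach from above for every
ion, and the quantitative 10% band for hydrogen.

# Mixing coefficients in a voxel

In a mixed field, each energy-deposition step of ion type t at energy i
contributes its database coefficients weighted by its share of the
voxel's deposited energy (the Kanai approximation):

$$\alpha_{mix} = \sum_{t,i} f_{t,i}\, \alpha_{t,i}, \qquad
  \beta_{mix} = \sum_{t,i} f_{t,i}\, \beta_{t,i}, \qquad
  f_{t,i} = \frac{E^{dep}_{t,i}}{E^{dep}}.$$

The voxel store keeps only three accumulators per occupied voxel —
$\sum E^{dep}$, $\sum E^{dep}\alpha$, $\sum E^{dep}\beta$ — in a sparse
hashed container, so streaming accumulation is order-independent and
exactly equals a two-pass batch evaluation (a tested invariant).
Coefficients are interpolated linearly in kinetic energy per nucleon;
out-of-grid queries clamp to the nearest node with a warning, never
extrapolating $\alpha$ below zero. Lookup uses the step-entrance energy,
which is well defined for the slice-based generator; step-length control
is delegated to the slice thickness.

From the mixed coefficients follow, per voxel: survival
$S_{mix}(D) = e^{-\alpha_{mix} D - \beta_{mix} D^2}$; the biological dose
as the inverse of the reference-photon LQ effect,

$$D_{bio} = \frac{-\alpha_{ref} + \sqrt{\alpha_{ref}^2 +
  4\beta_{ref}\,(\alpha_{mix} D + \beta_{mix} D^2)}}{2\beta_{ref}};$$

and RBE $= D_{bio}/D$ (undefined at D = 0 and reported as missing).
`rbe_at_survival()` gives the fixed-survival variants RBE10/RBE50 via the
generalized D10 inversion. The X-ray reference coefficients are mandatory
inputs — the published reference values for the validation experiment are
not available, so the tests use a synthetic reference (0.3 Gy$^{-1}$,
0.0615 Gy$^{-2}$) and say so. Per-voxel RBE10/RBE50 are computed from the
voxel's own mixed coefficients (the alternative, dose-averaged plateau
coefficients, is not what the per-voxel report layout implies).

# The synthetic beam and the SOBP

The generator emulates a 320 MeV/n carbon beam in a 15×15 cm² water
phantom of 250 × 1 mm slices, with all electronic losses deposited
locally (as in transport with secondary-electron production suppressed).
Transport is a Bragg–Kleeman surrogate $R = a E^p$ with $p = 1.75$ and a
calibrated once so that 320 MeV/n carbon ranges 220 mm; other species
scale as $A/Z^2$. Range straggling is Gaussian with $\sigma = 0.012 R$
(≈2.6 mm here), integrated *deterministically* by 61-node Gauss–Hermite
quadrature over the range distribution — a quadrature, not a sampler, so
runs are bit-reproducible and energy is conserved to 10⁻⁶ without
straggling and to 1% with straggling and attenuation (when the
attenuation toggle re-deposits the removed primaries' residual energy as
a helium-tagged tail; that toggle is crude plumbing, not fragmentation
physics, and is off by default). Fewer than ~30 quadrature nodes leaves
a visible comb artifact in the straggled peak; 61 resolves it well below
the slice width. The `seed` field in `beam_config()` is retained for
interface stability but nothing in the bundled transport is stochastic.

The SOBP builder composes range-shifted copies of the pristine beam with
non-negative least squares (Lawson–Hanson). The bundled thickness set is
the published 14-step aluminum ridge-filter description (6–32 mm);
because the range arithmetic works in water-equivalent millimetres they
are converted with the aluminum/water linear stopping ratio 2.1, which is
what lets a 32 mm filter span a 6 cm plateau. Design choices:

* the NNLS residual is restricted to the plateau rows (ridge-filter
  design constrains the plateau; entrance dose is whatever the physics
  gives), and flatness is max |d − mean|/mean over the window;
* the default 60 mm window is [149, 209] mm, centred on the region
  densely covered by the shifted peaks. The discrete 12.6 mm
  water-equivalent gap below the unshifted peak leaves a distal bump
  outside the plateau — an artifact of describing a continuous ridge
  filter by 14 steps, documented rather than hidden. Achieved physical
  flatness on the default fixture is ≈2.9%;
* duplicate thicknesses are deduplicated before solving; weights are
  non-negative by construction and adding a candidate curve never
  increases the residual (tested);
* the flat-*biological*-dose mode (constant survival across the SOBP)
  iterates fixed-point reweighting: solve for a physical target, push the
  records through the voxel actor, rescale the target by
  mean($D_{bio}$)/$D_{bio}(z)$, re-solve; at most 10 iterations or a 1%
  plateau spread, keeping the best evaluated iterate. On the default
  fixture it roughly halves the plateau biological-dose spread relative
  to the flat-physical solution.

The end-to-end run normalizes the composed field to 2.4 Gy at the
configured isocenter (defaulting to the SOBP centre; the experimental
prescription depth is not stated numerically in the source material) and
writes the per-voxel ASCII report (index, coordinates, $\alpha_{mix}$,
$\beta_{mix}$, D, $D_{bio}$, RBE). Across the plateau the RBE rises
monotonically into the distal edge in trend; the per-slice values carry
~1% ripple inherited from the discrete-peak dose structure, so the
monotonicity test uses a 9 mm moving average.

# What the synthetic data do and do not show

The generator reproduces the *structure* of a scored carbon field — a
Bragg peak at the calibrated range, slice-entrance energy tags, an
energy-conserving record stream, SOBP composition — and therefore
exercises every interface of the actor under controlled conditions. It
does **not** model lateral scattering, nuclear fragmentation spectra
(the helium tail is a labelled stand-in), beam-line materials, ripple
filters, or CT geometries; absolute biological doses and RBE for the
clinical beam line are out of reach without the original transport
simulation and coefficient databases, which is why the published
per-depth comparison values are shipped as *inputs* for
relative-difference arithmetic rather than recomputed. Passing tests
demonstrate internal consistency of the model chain and exact
reproduction of the published comparison arithmetic, not clinical
validation.

# Worked example

```{r example, eval = FALSE}
p <- mmkm_params()                       # HSG reference set
z0 <- saturation_parameter(p$Rd, p$Rn, p$beta)   # 48.98 Gy
sp <- single_event_spectrum("carbon", 50)        # f1(z) at 50 MeV/n
mmkm_alpha(p, z1d_star(sp, z0))$alpha            # ~0.95 /Gy

tab <- build_mmkm_table("carbon", default_energy_grid(40))
ref <- reference_radiation(0.3, 0.0615)          # synthetic X-ray reference
sobp <- normalize_to_prescription(build_sobp(), 2.4, 179)
rpt <- run_biodose_actor(sobp$records, tab, ref, phantom_geometry())
rpt[rpt$z %in% c(149.5, 179.5, 208.5), c("z", "dose", "dose_bio", "rbe")]
```

# Known limitations

* Amorphous-track microdosimetry ignores specific-energy fluctuations
  from delta-ray stochastics; for micrometre domains this is a few-percent
  effect, but it is the reason full track-structure codes exist.
* The Bethe/Barkas LET table is a standard parameterization, not a
  measured stopping-power compilation; agreement with reference tables
  is at the few-percent level over 0.1–400 MeV/n.
* The constant-$\beta$ assumption follows the mMKM parameterization and
  fails at very high LET where measured $\beta$ drifts.
* The 1-D fixture cannot reproduce absolute clinical depth-dose or RBE
  values; all quantitative claims about the real beam line are limited
  to the published comparison arithmetic.
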