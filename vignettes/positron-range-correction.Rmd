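---
title: "Positron range correction in iterative PET reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positron range correction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(petprc)
```

This vignette is the package's own account of its science: the transport
model and its assumptions, the kernel construction and composition rules,
how the resolution operator enters the reconstruction, the tunable
parameters with their defaults, what the synthetic phantoms do and do not
emulate, and the numerical choices made where the design was open.

## 1. Positron transport model

Positron kinetic energies are drawn from the allowed-transition Fermi
beta spectrum, N(T) ∝ p·E·(Q−T)²·F(Z,E), with the nonrelativistic
Coulomb function for positrons, F = 2πη/(1−e^(−2πη)), η = −αZ/β, where Z
is the daughter's atomic number. The Coulomb repulsion suppresses slow
positrons; for the ¹⁸F endpoint of 0.63 MeV the spectrum mean comes out
at 0.249 MeV, matching the accepted 0.25 MeV to better than 1 %.
Built-in decay schemes: ¹⁸F (Q = 0.63 MeV), ⁶⁸Ga (1.9 MeV), ¹²⁴I (two
branches at 1.54 and 2.14 MeV with relative intensities 0.52/0.48 — the
branching ratio is taken from standard nuclear data and is configurable,
since the two-branch structure, not the exact split, dominates the
range distribution).

Transport is condensed-history: per step the positron loses a fixed
fraction (default 3 %) of its kinetic energy through the collision
stopping power, advances by ΔE/(dE/dx), and is deflected by a multiple-
scattering angle drawn from a Rayleigh distribution whose scale is the
Highland plane-projected RMS, θ₀ = (13.6 MeV/βp)·√(x/X₀)·(1+0.038·ln(x/X₀)).
Below a 10 keV cutoff the positron annihilates in place. The stopping
power of water is evaluated from the Berger–Seltzer closed form for
positrons (mean excitation energy 75 eV, Z/A = 0.55509) over
10 keV–3 MeV; other media scale it by their electron density relative to
water (lung 0.257, bone 1.781, from mass density × Z/A). Radiation
lengths: 36.5 (lung), 36.08 (water), 28.8 g/cm² (bone).

Deliberate simplifications, and their observed cost:

* the density-effect correction to the stopping power is omitted (small
  below 3 MeV);
* annihilation-in-flight, bremsstrahlung transport and positronium
  formation are ignored;
* the Highland formula models only the Gaussian core of multiple
  scattering; the missing single-scattering tails under-estimate the
  path detour at high energies.

With 10⁵ events the simulated mean ranges in water are 0.51 mm (¹⁸F),
2.73 mm (⁶⁸Ga) and 2.71 mm (¹²⁴I), and 1.97 mm for ¹⁸F in lung. The ¹⁸F
values sit on the published full-Monte-Carlo values (0.50/1.96 mm); the
high-energy isotopes run 15–19 % long, inside the spread that different
full Monte Carlo codes report for the same quantity (2.32–2.69 mm for
⁶⁸Ga in water) and consistent with the Gaussian-core scattering
approximation above. In the voxelized variant of the transport the
medium is re-evaluated every step from the occupied voxel, with steps
additionally capped at half the smallest voxel pitch so borders are
never jumped.

## 2. Range kernels

A kernel is the normalized 3D histogram of annihilation offsets
(annihilation − emission) on an odd-sided voxel grid centered at the
emission voxel; offsets are assigned by `floor(offset/voxel + 0.5)` per
axis, i.e. the emission point sits at the exact center of the center
voxel. Events outside the grid are dropped and counted. The half width
is `ceil(max_range/voxel)`; the governing `max_range` defaults to 10 mm
(the lung range of ¹⁸F and the water range of ⁶⁸Ga/¹²⁴I), which gives
the canonical 11×11×11 kernel at 2.036 mm pitch. Whether "maximum range"
means the absolute maximum or a high percentile is left open by the
sizing rule, so `max_range` is an explicit parameter.

Material classification thresholds a 511 keV µ-map at 0.08 and
0.12 cm⁻¹ into lung/water/bone. The spatially variant kernel at voxel j
takes, for each offset u, the value of the uniform kernel of the
material at the **destination** voxel j+u, then renormalizes to sum 1.
Destination-side (annihilation-side) sampling is the interpretation
consistent with partitioning the kernel region by the surrounding map,
and with the known failure mode of this approximation — over-estimated
kernel values where a positron emitted in a dense material crosses into
lung, because the composition ignores the energy already lost in the
dense material. Offsets whose destination falls outside the image clamp
to the nearest in-image voxel for the material lookup; renormalization
happens after clamping. Deep inside homogeneous tissue the composition
returns the uniform kernel bitwise (a fast path copies it verbatim).

Three provider modes expose the correction hierarchy: `uniform_water`
(one water kernel everywhere), `tissue_dependent` (the voxel's own
material kernel, borders ignored), `spatially_variant` (full
composition). Per-voxel kernels are composed on demand during the
reconstruction, never pre-stored — at clinical image sizes the full set
would not fit in memory.

Validation against direct simulation: simulating the source in the
heterogeneous boxes of `make_kernel_validation_phantom()` and binning
the cloud gives a reference kernel; the composed kernel is closer to it
(L1) than either homogeneous kernel, with the residual concentrated at
the material border, as expected from the energy-loss approximation.

## 3. Reconstruction

The system matrix is A = WXH. X is a slice-parallel 2D parallel-beam
projector with exact voxel–ray intersection lengths; one traversal
routine produces the coefficients for the forward projection, the back
projection and the attenuation line integrals, which makes Xᵀ the exact
adjoint by construction. W = exp(−Σ x·µ/10) carries attenuation only;
geometric sensitivity is modeled as uniform. H is applied as per-voxel
scatter; mass leaving the field of view is dropped *without*
renormalization, which keeps Hᵀ an exact transpose (the kernel-level
renormalization of §2 is a separate, per-kernel operation). The PR blur
is fully 3D across slices even though projections are slice-parallel.

The OSEM update with PRC blurs the current estimate (H f), projects,
back-projects the data ratio, applies Hᵀ, and divides by the blurred
subset sensitivity Hᵀ Xᵀ w. The update is multiplicative, so iterates
stay non-negative; voxels whose subset sensitivity falls below 1e−8 of
its maximum are frozen at zero; the projection denominator is guarded by
ε = 1e−10. Subsets are fixed interleaved (angle k → subset k mod n), a
reproducibility-over-variance-reduction choice. The initial image is
uniform 1 inside the sensitivity-defined FOV. No post-filter is applied
anywhere. Attenuation enters the sensitivity only; the acquisition
simulator therefore produces attenuation-precorrected data by default,
with a flag to include W in the data mean for self-consistency
experiments (Poisson noise on precorrected data is itself an
approximation, acceptable at these count levels).

With one subset and a provider the update is MLEM on the composed model
WXH, and the surrogate Poisson likelihood is non-decreasing — asserted
numerically in the tests for both the plain and the blurred model. An
identity (delta-kernel) provider reproduces plain OSEM bitwise.

## 4. Phantoms and the comparison protocol

All experiments run on synthetic phantoms sharing one grid per bundle:

* **NEMA-like IQ phantom** — elliptical water body (semi-axes
  112 × 87 mm), six spheres (10–37 mm) on a 57.2 mm ring, default fill
  30/6 kBq/ml (5:1; 24/3 for the ⁶⁸Ga protocol). Twelve 37 mm background
  VOIs sit on a 75 mm ring, six each at z = ±18.5 mm; sphere-to-angle
  assignment was chosen once so every background VOI is provably
  disjoint from every sphere, and the constructor enforces this. The
  default grid is 128×128×37 at 2.036/2.027 mm — the 37 mm sphere plus
  axially offset VOIs need ≈75 mm of axial coverage, which a 15-slice
  desk grid cannot hold.
* **Resolution phantom** — 16 sub-voxel point sources on a 4×4
  transverse grid (30 mm spacing) in the water housing, deposited with
  trilinear weights so all sources carry exactly equal activity; central
  2×2 labeled *inner*, corners *outer*.
* **Bone–lung phantom** — three 50 mm cylinders (−800/500/1000 HU,
  converted to µ by the bilinear HU mapping anchored at air, water and
  1000 HU bone) in the water body, each holding hot 8.5 and 19.4 mm
  spheres at 5:1 over the water background; cylinders are cold.
  (The 28 mm NEMA sphere and the 8.5 mm insert follow the consistent
  subset of the published phantom descriptions.)

Sphere voxelization uses 3× supersampled partial-volume weights; sphere
and tube walls are not modeled (sub-voxel structures are treated as the
surrounding medium — a known limitation that over-states the range in
real wall-bearing phantoms). VOI membership for metrics is by voxel
center, without partial-volume weighting, and the background noise
statistic uses the sample (n−1) standard deviation, averaging per-VOI
standard deviations and per-VOI means separately.

**Noise-matched comparison.** Arms (e.g. OSEM vs PRC) share the phantom,
counts and seed; each runs over an iteration range; each is read out at
the first iteration whose background noise reaches the target. At the
desk-scale count level of 5×10⁶ the background-noise floor after one
OSEM iteration is already ≈29 % (clinical acquisitions giving ~10 %
noise carry far more counts), so the driver raises the matching target
to the noisiest arm's floor and matches there — the arms are then
compared at genuinely comparable noise (≈29 % vs ≈32 % in the worked
example) rather than at nominally equal but unreachable 10 %.

What passing these experiments shows — and does not. The acquisition
simulator uses the same operator family as the reconstruction (an
inverse crime, deliberate for operator-correctness and directional
tests; a different provider can be passed to the simulator for
model-mismatch studies). Scatter, randoms, detector blur, TOF and decay
are absent. Directions (PRC recovers small-sphere contrast at matched
noise, converges more slowly, sharpens point sources for wide kernels
and leaves ¹⁸F essentially unchanged) transfer to real data; absolute
recovery values do not.

## 5. Parameter summary

| Parameter | Default | Units | Notes |
|---|---|---|---|
| energy cutoff | 10 | keV | local annihilation below it |
| max fractional energy loss / step | 0.03 | – | step control |
| kernel `max_range` | 10 | mm | side 11 at 2.036 mm pitch |
| µ thresholds | 0.08 / 0.12 | cm⁻¹ | lung/water/bone |
| OSEM iterations (plain / PRC) | 2 / 8 | – | with 12 subsets |
| ratio guard ε | 1e−10 | – | projection denominator |
| sensitivity floor | 1e−8·max | – | freezes dead voxels |
| counts (experiments) | 5×10⁶ | – | desk-scale acquisitions |
| transport events (kernels) | 10⁵ | – | per material |

Problem sizes were chosen for single-CPU desk-scale runs: 10⁵-event
transport batches, 128×128×37 reconstructions with 120 angles and 12
subsets, and 10⁵-event kernels; all are parameters, not limits of the
implementation.

## 6. Known limitations

* Composition ignores the positron's energy-loss history across borders
  (over-estimation on the low-density side of a dense→light crossing) —
  inherent to the method, visible in the validation comparisons.
* Transport omits annihilation-in-flight and scattering tails; ranges
  for Q ≳ 1.5 MeV are biased long by ~15–19 % relative to full Monte
  Carlo, within the inter-code spread.
* The projector is 2D slice-parallel (no oblique LORs); the blur is 3D.
* Gibbs-type edge overshoot at sharp activity borders is expected of any
  resolution-modeling reconstruction and is not post-filtered.
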