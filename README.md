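# petprc

Spatially-variant, tissue-dependent positron range correction (PRC) for
PET image reconstruction, with everything needed to study it on synthetic
data: a condensed-history positron transport Monte Carlo, per-material 3D
range kernels, voxel-specific kernel composition from a 511 keV
attenuation map, an OSEM reconstruction whose forward *and* back
projections carry the range blur, digital NEMA-style phantoms, and the
standard phantom evaluation metrics.

## The problem

A positron travels a finite distance between emission and annihilation
(the *positron range*), so PET localizes annihilations, not emissions.
For ¹⁸F (E_max = 0.63 MeV) the mean range in water is ~0.5 mm and the
effect is negligible, but for ⁶⁸Ga (E_max = 1.9 MeV) and ¹²⁴I (two
branches, 1.54/2.14 MeV) it reaches 2–3 mm in water and ~9 mm in lung,
blurring images and destroying small-lesion contrast. The range
distribution depends strongly on tissue density, so a single blurring
kernel is wrong in heterogeneous anatomy.

## The method

The system matrix is factorized as **A = W X H**, where **X** holds exact
voxel–ray intersection lengths (ray-driven Siddon-style projector),
**W** the per-LOR attenuation factors, and **H** the positron-range
resolution operator. The column of **H** at voxel *j* is a normalized 3D
kernel built in three steps:

1. **Simulate**: point sources of the isotope in homogeneous lung, water
   and bone; annihilation displacements `r = |x_f − x_i|` are histogrammed
   on the PET voxel grid into *uniform kernels* sized by the governing
   maximum range (side `2·ceil(r_max/voxel)+1`, i.e. 11 voxels for 10 mm
   at 2.036 mm pitch).
2. **Classify**: threshold the 511 keV µ-map — µ < 0.08 cm⁻¹ lung,
   0.08–0.12 water, ≥ 0.12 bone.
3. **Compose**: for each voxel, assemble a voxel-specific kernel by
   taking, at every kernel offset u, the value of the uniform kernel of
   the material at the destination voxel j+u, then renormalize.

The OSEM update then becomes

```
f_j ← f_j · [ Hᵀ Xᵀ_S ( m_S / (X_S H f) ) ]_j / [ Hᵀ Xᵀ_S w_S ]_j
```

with the blur applied in both the forward and the back projection —
the back projector stays the exact transpose of the forward operator.
Simplified variants are provided: one water kernel everywhere
(`uniform_water`, PRC-Unif) and per-voxel tissue kernels ignoring
borders (`tissue_dependent`, PRC-TD).

## Worked example

```r
library(petprc)

# mean positron range of Ga-68 in water (1e5 events)
cl <- simulate_point_source("Ga68", "water", 1e5, seed = 1)
range_statistics(cl)$mean
#> [1] 2.725559

# kernel library and a range-corrected reconstruction of a NEMA-like
# phantom at 5e6 counts
res <- run_experiment(experiment_config(
  phantom = "nema", isotope = "Ga68", counts = 5e6, seed = 1,
  arms = list(osem = list(prc_mode = "none", n_iterations = 6),
              prc  = list(prc_mode = "uniform_water", n_iterations = 8))))

res$matched_iteration
#> $osem
#> [1] 1
#> $prc
#> [1] 4
round(res$curves$osem[1, c("noise", "rc_10mm")], 3)
#>    noise rc_10mm
#> 1 29.144   0.426
round(res$curves$prc[4, c("noise", "rc_10mm")], 3)
#>    noise rc_10mm
#> 4 32.148   0.704
```

At comparable background noise (~29 % vs ~32 % at this count level), the
range-corrected arm recovers 0.70 of the 10 mm sphere's true contrast
against 0.43 for plain OSEM — the same direction and magnitude class of
improvement reported for ⁶⁸Ga/¹²⁴I on measured phantoms — while
converging more slowly per iteration (the blur in the back projection
acts like regularization).

A thin CLI over the same functions is installed at
`inst/cli/petprc.R` (subcommands `simulate-range`, `build-kernels`,
`material-map`, `make-phantom`, `reconstruct`/`run-experiment`,
`validate-kernels`, ...).

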