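# scatomo

Scanning X-ray scattering tomography of plant tissue in R.

Plant stems scatter X-rays in a characteristic way: crystalline cellulose
produces sharp diffraction peaks (the (020) reflection near q = 1.6 Å⁻¹),
amorphous matrix polymers a broad halo, A-type starch its peak triplet at
q ≈ 1.07 / 1.21 / 1.27 Å⁻¹, and packing correlations between cellulose
microfibrils a diffuse SAXS peak near 0.1 Å⁻¹. When a stem is scanned across
a micro-focused beam at a series of rotation angles about its growth axis,
the azimuthally integrated intensity

&nbsp;&nbsp;&nbsp;&nbsp;I_o(q) = ∫ I(q, φ) dφ

is invariant under sample rotation, so any scalar feature derived from it is
additive along the beam and obeys the Radon transform. That turns a scanning
scattering experiment into tomography: feature sinograms I(x, R_y) reconstruct
into virtual cross-sections of cellulose, starch, SAXS intensity, the Segal
crystallinity index

&nbsp;&nbsp;&nbsp;&nbsp;CI = (I_c′ − I_a′) / I_c′,

NMF component maps with per-voxel recomposed scattering profiles
I(q; x, y) = Σ_c M_c(x, y) V_c(q) / s(q), composition clusters, and — from
the azimuthal splitting of the equatorial cellulose reflection at ±MFA —
microfibril-angle maps via regularized non-negative least squares
x = argmin_{x≥0} ‖y − Ax‖² + λ₁‖x‖² + λ₂‖Dx‖² on a discrete-MFA basis
(0–90° in 3° steps, intrinsic width 5°), summarized per voxel by the nominal
angle φ_a = Σ|φ|I(φ) / ΣI(φ).

The package is written for beamline users and plant-science groups who want
to prototype or validate this workflow before (or instead of) committing to
beamtime: every stage is exercised end-to-end against a forward simulator of
annular stem phantoms, so each analysis step can be judged by how well it
recovers planted ground truth.

## What is in the box

| Stage | Functions |
|---|---|
| Phantoms + forward scan simulator | `build_component_library()`, `make_ring_phantom()`, `make_blob_phantom()`, `simulate_scan()` |
| Frame reduction | `q_from_angle()`, `azimuthal_average()`, `equatorial_profile()`, `correct_frame()`, `correct_scan()`, `rolling_ball()`, `q_smearing()` |
| Feature maps | `build_sinogram()`, `segal_ci()`, `damage_score()`, `feature_windows()` |
| Reconstruction | `radon()`, `fbp()`, `iterative_recon()` (MLEM/SIRT), `find_center()`, `normalize_tomogram()` |
| NMF decomposition | `shape_factor()`, `fit_nmf()`, `select_rank()`, `decompose_scan()`, `recompose_voxels()` |
| Clustering | `normalize_composition()`, `kmeans_segment()`, `inertia_curve()`, `cluster_profiles()` |
| MFA analysis | `projection_averaged_profile()`, `build_mfa_basis()`, `nnls_regularized()`, `nominal_mfa()`, `per_phi_tomograms()`, `mfa_maps()` |
| Orchestration | `pipeline_config()`, `open_container()`, `run_stage()`, plus a CLI at `inst/cli/scatomo.R` |

## Worked example

Simulate a rice-like stem (cellulose + amorphous wall, starch accumulating
on the inner periphery, microfibril angle rising from 5° at the outer rim to
30° at the inner rim), reduce it, and reconstruct the crystallinity map:

```r
library(scatomo)

comps <- build_component_library(seq(0.04, 2, by = 0.02))
ph    <- make_ring_phantom(n_voxels = 48, voxel_size = 5,
                           outer_radius = 105, wall_thickness = 55,
                           mfa_outer = 5, mfa_inner = 30)
scan  <- simulate_scan(ph, comps,
                       acquisition_config(angles = seq(0, 180, by = 3)),
                       phi_grid = seq(-90, 90, by = 3))
scan  <- correct_scan(scan)                    # absorption correction

center <- find_center(absorption_sinogram(scan))
wins   <- feature_windows("bamboo")
cell   <- build_sinogram(scan, wins$cellulose, feature = "cellulose")
amor   <- build_sinogram(scan, wins$amorphous, feature = "amorphous")
ci <- segal_ci(
  normalize_tomogram(iterative_recon(cell, "mlem", center = center), cell),
  normalize_tomogram(iterative_recon(amor, "mlem", center = center), amor),
  diff(wins$cellulose), diff(wins$amorphous))
mean(ci$values, na.rm = TRUE)
#> [1] 0.2365545

stack <- per_phi_tomograms(scan, c(1.55, 1.65))
mm    <- mfa_maps(stack, build_mfa_basis(stack$phi_grid),
                  distributions = FALSE)
range(mm$phi_a$values, na.rm = TRUE)
#> [1]  8.458311 41.689890
plot(mm$phi_a)
```

The CI map is monotone in the planted crystalline fraction (Spearman
ρ > 0.95 in the test suite), though — as with any Segal-type index — its
absolute level depends on the window conventions and is read comparatively.
The φ_a map rises from the outer to the inner rim, tracking the planted
5→30° gradient with Spearman ρ ≈ 0.998 against the planted field; its range
(8.5–41.7°) brackets the planted angles because φ_a is an intensity-weighted
mean, not a calibrated MFA. Or run the whole chain at once:

```r
cont <- open_container(tempfile())
run_stage("all", pipeline_config("rice"), cont)   # simulate ... report
```

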