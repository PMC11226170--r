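---
title: "Scanning scattering tomography of plant stems: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning scattering tomography of plant stems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(scatomo)
```

## The measurement model

A plant stem mounted with its growth direction on the rotation axis is
scanned across a micro-focused X-ray beam at a series of projection angles
`R_y`. Each frame is a q–φ intensity map: momentum transfer
`q = 4π sin θ / λ` (with `λ = 12.3984 / E` Å at energy `E` in keV) against
the azimuthal angle φ on the detector, with φ = 0 on the equator of the
fiber-diffraction geometry. Two facts make this dataset tomographic:

1. **Rotational invariance.** Scattering from a cellulose fibril is
   invariant under rotation about the fiber axis, and the azimuthally
   integrated intensity `I_o(q)` of a voxel does not change as the stem
   rotates about the growth direction. Any scalar derived from `I_o` is
   therefore additive along the beam and obeys the Radon transform.
2. **Azimuthal encoding of the microfibril angle (MFA).** Cellulose
   microfibrils wound at angle μ to the growth axis split the equatorial
   reflections into a symmetric pair of azimuthal peaks at φ = ±μ. Averaged
   over all projection angles, every cell-wall orientation contributes
   equally, so the azimuthal profile of the cellulose peak reflects the
   sample's MFA distribution alone.

The package implements the full chain — frame reduction, feature sinograms,
reconstruction, NMF decomposition, clustering, MFA analysis — together with
a forward simulator, so that each stage can be validated by recovering
planted ground truth. Everything the tests and the acceptance script assert
is computed by these functions at run time; this vignette explains the
models and the choices behind them.

## The forward simulator

`simulate_scan()` projects a `tissue_phantom` (per-component concentration
maps, an MFA field, an attenuation map) through the same sparse Radon
operator used for reconstruction. Each frame is

I(q, φ) = Σ_c [line integral of conc_c · G_c(φ; mfa)] · S_c(q) · T · d,

where `S_c` is the component spectrum, `G_c` is flat for isotropic
components (amorphous matrix, starch) and a ±MFA Gaussian pair with σ = 5°
for equatorial ones (crystalline cellulose, the fibril-correlation SAXS
peak), `T = exp(−∫μ)` is the Beer–Lambert transmission recorded in the
monitors, and `d` is an optional per-frame damage decay. Poisson noise is
applied at a configurable photon scale (0 = noiseless, the default study
condition; all recovery criteria are defined on noiseless scans).

Two modelling points deserve emphasis:

* **Voxel-additive azimuthal emission.** Each voxel contributes its own
  ±mfa(voxel) envelope and the detector sums the line integrals per φ bin.
  An alternative — a single envelope at the concentration-weighted mean MFA
  of the ray — looks similar per frame but violates the additivity along the
  beam that per-voxel azimuthal reconstruction relies on; with it, per-voxel
  MFA recovery would fail for reasons unrelated to the analysis. The
  voxel-additive model is also the physically correct superposition.
* **Matched azimuthal width.** The simulator's σ = 5° equals the intrinsic
  width of the MFA analysis basis, so the MFA inversion is exact in
  principle and any recovery error is attributable to reconstruction and
  regularization, not model mismatch. The "intrinsic width" is interpreted
  as a Gaussian σ (not FWHM) on both sides consistently.

`build_component_library()` provides stand-in spectra: Gaussian cellulose
reflections at q = 1.05, 1.17, 1.60 Å⁻¹ (σ = 0.02, the last inside the
standard 1.55–1.63 integration window), a broad amorphous halo (center
1.35 Å⁻¹, σ = 0.30), A-type starch peaks at 1.07/1.21/1.27 Å⁻¹ (σ = 0.015),
and a fibril-correlation peak at 0.10 Å⁻¹ on a q⁻³ porosity power law
clipped below 0.03 Å⁻¹. These are plausible line shapes landing in the
printed feature windows, not fits to any measured profile.

`make_ring_phantom()` is the standard study object: an annular culm wall
whose crystalline fraction interpolates radially (0.75 at the outer rim to
0.35 at the inner rim by default), starch rising *quadratically* toward the
inner periphery (a localized storage profile; a linear profile would make
the three concentration fields exactly linearly dependent — a measure-zero
degeneracy no real tissue has), an MFA field interpolating 5°→30° outer to
inner (sclerenchyma-like low MFA at the surface), and attenuation
proportional to total concentration. Default geometry: 48–64 voxels at
5 µm, outer radius ≈ 105–140 µm — a stem section scaled so a desk machine
can simulate hundreds of frames in seconds; the acquisition default is the
survey geometry of 121 angles at 1.5° with interleaved groups of eight.

## Frame reduction

`correct_frame()` / `correct_scan()` subtract the empty-beam background
scaled by the transmitted intensity and divide by the transmission, so
corrected intensity is proportional to scattering material per beam path.
Measured (uncorrected) frames carry the Beer–Lambert factor and are *not*
rotation-invariant; the invariance tests operate on corrected data, which
reaches ≈0.1% relative spread of the angle-wise `I_o` totals on the default
phantom (the module contract is ≤0.5%; exact equality is unattainable for
any discretely sampled projector, whose sampling lattice rotates with the
angle). Negative intensities after subtraction are clipped to zero and
counted, because the downstream NMF and NNLS stages require non-negative
data.

`rolling_ball()` implements the 1-D baseline as a grey-scale opening
(minimum then maximum filter, window `2·radius + 1` bins) with
linear-slope edge padding, followed by spike clamping at
`baseline + k·MAD` (k = 5 default). The opening passes under features wider
than the window and excludes narrower ones, which is what separates sharp
starch peaks (σ = 0.015 Å⁻¹) from the broad halo, and sharp cuticular-wax
spikes from everything else. Its known limitation is curvature: under a
dome of width comparable to the window the flat chord sits a few percent
low, so baseline-subtracted windows retain a small leakage of very broad
components (measured ≈5% of the cellulose-window signal in the starch2
window on the default library). The same limitation applies to the
amorphous subtraction in the MFA stage: the q = 1.8–1.9 Å⁻¹ estimate
under-subtracts a sloping halo, leaving a φ-flat pedestal. The pedestal has
no azimuthal structure, so rank-based MFA statements (gradients, maxima
positions) are unaffected, but absolute φ_a values are biased toward 45°
and should be read comparatively.

## Feature sinograms and the crystallinity index

`build_sinogram()` integrates `I_o` over a closed window (trapezoid, both
endpoints inclusive, matching how printed ranges are stated), optionally
after rolling-ball baseline subtraction (starch). Windows live in
`feature_windows()`: SAXS 0.10–0.15; bamboo-type cellulose 1.55–1.63 and
amorphous 1.28–1.37; rice-type starch 1.10–1.18 and 1.25–1.32 with
cellulose 1.45–1.55 and amorphous 1.30–1.35. One caveat discovered in
validation: the library's 1.17 Å⁻¹ cellulose reflection sits inside the
1.10–1.18 starch window, so with these stand-in spectra only the
1.25–1.32 window is starch-specific; the beamline windows were chosen
against measured spectra where this overlap is absent.

`segal_ci()` divides each window integral by its width (so differently wide
windows are comparable), excludes voxels below 5% of the cellulose-map
maximum (a division-by-zero guard; the threshold is a design default, not a
physical constant) and clips CI into [0, 1] with a logged count. CI is
monotone in the planted crystalline fraction (Spearman ρ > 0.95 on the
default phantom) but its absolute level is convention-dependent, as is true
of Segal-type indices generally.

`damage_score()` reports the maximum angle-adjacent row-total jump
normalized by the median row total. Interleaved acquisition places
angle-neighbours far apart in time, so decay between groups appears as a
discontinuity; the planted-decay test shows the score separating a damaged
scan from a clean one by more than an order of magnitude.

## Reconstruction

All projection and backprojection go through one cached sparse system
matrix (`radon_matrix()`): each (angle, detector-bin) ray samples the image
at half-pixel steps along the beam with bilinear weights. Forward and back
projection are exact transposes, which gives MLEM its monotone Poisson
likelihood (asserted numerically in the tests) and makes SIRT stable. The
half-step oversampling keeps the projection mass angle-independent to
≈0.1%; unit-step sampling showed ≈0.3–0.5% ripple on thin annuli.

`fbp()` uses the discrete Ram–Lak kernel in real space (h(0) = 1/4,
h(odd k) = −1/(π²k²)) and masks voxels outside the inscribed circle, which
leave the detector at some angles and otherwise accumulate a negative bias.
`iterative_recon()` defaults to 100 iterations, the working value for this
kind of data. On the 200×200 annulus at 121 angles both FBP and MLEM
correlate with truth at ≥0.99; the acceptance criterion is ≥0.95.

`find_center()` registers the 0° projection against the mirrored 180°
projection. The rows are stripped of their 5th-percentile level and clipped
at zero, so the correlation is weighted by object mass only — this is what
makes the estimate invariant to constant offsets and free of the
overlap-length bias that plagues plain SSD scoring — and the discrete
argmax is refined by a parabolic fit (planted shifts recover to < 0.1 px).
All reconstructions of one dataset reuse a single center value.
`normalize_tomogram()` rescales each map so its total equals the mean
sinogram row total, making values comparable across features.

## NMF decomposition and its identifiability limit

Profiles are pre-scaled by `shape_factor()` — normalized q², clipped below
at 10⁻⁴ — which compresses the several-decade dynamic range so the
Frobenius loss does not ignore weak high-q features; recomposition divides
by the identical factor. `fit_nmf()` defaults to HALS (the
coordinate-descent family that is the reference default in scikit-learn)
with non-negative-double-SVD initialization; classic multiplicative updates
are available but converge too slowly to reach the planted-factorization
residuals the validation demands (measured: 4·10⁴ MU iterations still above
10⁻³ relative residual on exact rank-3 data). Both keep the objective
non-increasing. `select_rank()` reports the residual curve (warm-started
across ranks so it is monotone rather than jumping between local minima)
and, independently, the count of singular values above 1% of the leading
one.

Validation exposed a genuine identifiability boundary worth understanding.
On an annular wall phantom, *every* beam path crosses the wall, so no frame
is dominated by a single wall component; the data then span a narrow cone
whose extreme rays are the most-cellulose-rich and most-amorphous-rich
*mixtures*, and any exact NMF returns those mixtures, not the pure
components (cellulose-map correlation plateaus near 0.76 regardless of
solver accuracy). This is the same non-uniqueness observed on real data,
where NMF components "do not correspond to physical constituents". The
package therefore ships `make_blob_phantom()` — disjoint single-component
domains, so near-pure frames exist — as the decomposition validation
object; on it, component maps recover at ρ ≈ 0.99 and the 1%-SVD rule finds
the planted rank. The ring phantom remains the study object for CI and MFA,
where identifiability is not at stake. `recompose_voxels()` and
`cluster_profiles()` recompose actual scattering intensities from component
amplitudes; the latter is what makes k-means centroids interpretable even
when individual NMF vectors are not.

## Clustering

`normalize_composition()` scales each voxel's component vector to unit
length — composition, not abundance, drives the segmentation — and excludes
voxels below 5% of the maximum total (shared with the CI mask default).
`kmeans_segment()` runs Lloyd iterations from k-means++ seeds, best of 10
restarts; k-means is initialization-sensitive and restarts are cheap at
this problem size. The default of three clusters keeps label maps readable;
`inertia_curve()` exposes the elbow so the user can choose otherwise, since
there is rarely a single best value.

## MFA analysis

`projection_averaged_profile()` averages all frames, integrates the
cellulose-peak window per φ and subtracts the width-scaled isotropic
estimate from q = 1.8–1.9 Å⁻¹ (see the pedestal caveat above).
`build_mfa_basis()` discretizes MFA at 0–90° in 3° steps (31 values) as
unit-integral ±μ Gaussian pairs with σ = 5°; higher-order cellulose layer
lines are ignored. The geometric cell-wall arc mapping used in some
wood-science work is deliberately not reproduced — the plain ±μ basis is
the self-consistent counterpart of the simulator's envelope.

`nnls_regularized()` solves the stacked system
`[A; √λ₁ I; √λ₂ D] x ≈ [y; 0; 0]` with non-negativity (Lawson–Hanson via
`pracma::lsqnonneg`), where `D` is the first-difference operator (+1 on the
diagonal, −1 directly below — the matrix whose quadratic form penalizes
differences of neighbouring weights). The profile is max-normalized
internally purely for numerical conditioning; the objective itself is
scale-equivariant. Defaults λ₁ = 0.01, λ₂ = 0.1 are sensible smoothing for
noisy profiles but *do* broaden delta-like distributions (the weights `x`
are numerically much larger than the unit-normalized profile, so the
penalties bite harder than their nominal size suggests); the noiseless
recovery analyses use λ = 10⁻³, and λ should generally be tuned per dataset
— they are exposed in every entry point. The solution is verified against a
brute-force active-set enumeration (a global QP oracle) to 10⁻⁶ in the
tests.

`per_phi_tomograms()` reconstructs one map per azimuthal bin (FBP with
clipping by default — 61 reconstructions are cheap through the shared,
cached projector; MLEM is available), reusing the dataset-wide rotation
center, and `mfa_maps()` derives per-voxel φ_a and (optionally) full NNLS
distributions with low-intensity masking. On the default gradient phantom,
per-voxel φ_a tracks the planted 5→30° field at Spearman ρ ≈ 0.998; the
whole-sample distribution of a constant-18° phantom is recovered within one
basis step (earth-mover distance ≤ 3°). As with the source method, the
per-voxel results are validated only against the package's own simulator
and should be treated as qualitative on real data until validated against
an independent measurement.

## Orchestration, sizes and limits

`run_stage()` drives simulate → reduce → maps → nmf → cluster → mfa →
report over a directory-backed container (one serialized dataset per
hierarchical name plus a YAML manifest carrying stage, seed, config hash
and package version); a thin command-line front end lives at
`inst/cli/scatomo.R`. Every stage is deterministic given the config and
seed, and reruns reproduce outputs bit for bit.

Default problem sizes (48-voxel sections, 61 angles, 3° azimuthal bins,
0.01–0.02 Å⁻¹ q steps; 200 voxels for the reconstruction benchmarks) were
chosen so the whole validation suite runs in about two minutes on a single
CPU while keeping every recovery margin wide; all of them scale up by
changing the config only.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: cell-level microstructure and wall-geometry
effects on the azimuthal profile, position shifts of the fibril-correlation
peak with packing density (a single SAXS component cannot represent a
moving peak), detector geometry, polarization/Lorentz and solid-angle
corrections, fluorescence, and real-beamline backgrounds. The phantom
spectra are stand-ins with Gaussian line shapes; real spectra would change
absolute window integrals, CI levels and NMF components, though not the
additivity and invariance properties the tomography rests on.
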