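# Ground-truth plant-stem phantoms and the forward scan simulator.
#
# The simulator emulates a scanning scattering-tomography measurement of a
# stem cross-section: at each projection angle the sample is translated
# across the beam and every frame records a q-phi intensity map plus
# incident/transmitted monitors. Scattering is voxel-additive: each voxel
# contributes conc_c * S_c(q) * G_c(phi) where G_c is flat for isotropic
# components and, for equatorial components (crystalline cellulose, the
# fibril-correlation SAXS peak), a symmetric Gaussian pair at +/- the voxel's
# microfibril angle with sigma = 5 degrees. The azimuthal integral of G_c is
# the same for every MFA, so the azimuthally integrated profile I_o(q) is
# invariant under sample rotation -- the property that makes scalar
# tomographic reconstruction valid.

#' A named component scattering spectrum
#'
#' @param name label.
#' @param q_grid momentum transfer grid, inverse Angstrom.
#' @param intensity non-negative profile, arbitrary units.
#' @param azimuthal_class `"equatorial"` (carries the +/-MFA azimuthal
#'   modulation) or `"isotropic"`.
#' @return object of class `component_spectrum`.
#' @export
component_spectrum <- function(name, q_grid, intensity,
                               azimuthal_class = c("isotropic", "equatorial")) {
  azimuthal_class <- match.arg(azimuthal_class)
  if (any(intensity < 0)) abort2("intensity must be >= 0", "scatomo_value_error")
  if (any(diff(q_grid) <= 0))
    abort2("q_grid must be strictly increasing", "scatomo_grid_error")
  structure(list(name = name, q_grid = as.numeric(q_grid),
                 intensity = as.numeric(intensity),
                 azimuthal_class = azimuthal_class),
            class = "component_spectrum")
}

.gauss <- function(q, mu, sigma, h = 1) h * exp(-0.5 * ((q - mu) / sigma)^2)

#' Reference library of plant-tissue component spectra
#'
#' Stand-in spectra for the structural components seen in plant-stem
#' scattering: crystalline cellulose (Gaussian reflections at q = 1.05, 1.17
#' and 1.60 1/A, the last being the (020) peak inside the 1.55-1.63 window),
#' a broad amorphous halo (lignin and other matrix polymers), A-type starch
#' (sharp peaks at q = 1.07, 1.21 and 1.27 1/A), and the fibril-correlation
#' SAXS peak near 0.1 1/A riding on a q^-3 porosity power law (clipped below
#' q = 0.03). Peak shapes are Gaussian; positions land inside the standard
#' feature-integration windows.
#'
#' @param q_grid momentum transfer grid covering at least `[0.05, 2.0]` 1/A.
#' @return named list of [component_spectrum()] objects:
#'   `cellulose`, `amorphous`, `starch`, `saxs`.
#' @export
build_component_library <- function(q_grid) {
  if (min(q_grid) > 0.05 + 1e-9 || max(q_grid) < 2.0 - 1e-9)
    abort2("q_grid must cover [0.05, 2.0] 1/A", "scatomo_config_error")
  cellulose <- .gauss(q_grid, 1.05, 0.02, 0.4) +
    .gauss(q_grid, 1.17, 0.02, 0.3) + .gauss(q_grid, 1.60, 0.02, 1.0)
  amorphous <- .gauss(q_grid, 1.35, 0.30, 1.0)
  starch <- .gauss(q_grid, 1.07, 0.015, 0.8) +
    .gauss(q_grid, 1.21, 0.015, 0.6) + .gauss(q_grid, 1.27, 0.015, 1.0)
  powerlaw <- 0.02 * pmax(q_grid, 0.03)^(-3)
  saxs <- .gauss(q_grid, 0.10, 0.02, 1.0) + powerlaw
  list(
    cellulose = component_spectrum("cellulose", q_grid, cellulose, "equatorial"),
    amorphous = component_spectrum("amorphous", q_grid, amorphous, "isotropic"),
    starch    = component_spectrum("starch", q_grid, starch, "isotropic"),
    saxs      = component_spectrum("saxs", q_grid, saxs, "equatorial")
  )
}

#' Annular plant-stem phantom
#'
#' A hollow-cylinder cross-section (culm wall) on an `n_voxels` square grid:
#' a cellulose + amorphous wall whose crystalline fraction interpolates
#' radially, starch concentrated toward the inner periphery when
#' `starch_gradient > 0`, a radial microfibril-angle field interpolating from
#' `mfa_outer` at the outer rim to `mfa_inner` at the inner rim, and linear
#' attenuation proportional to total concentration. The annulus fits inside
#' the inscribed circle of the grid so projection mass is angle-independent.
#'
#' @param n_voxels grid side length.
#' @param voxel_size voxel edge, micrometre (default 5).
#' @param outer_radius,wall_thickness annulus geometry, micrometre;
#'   `wall_thickness < outer_radius` and the annulus must fit the grid.
#' @param wall_density total wall concentration (arbitrary units).
#' @param crystallinity_outer,crystallinity_inner crystalline fraction of the
#'   wall at the outer / inner rim (linear radial interpolation).
#' @param starch_gradient peak starch concentration at the inner rim; the
#'   starch map rises quadratically from 0 at the outer rim, concentrating
#'   starch in the innermost tissue. `0` gives no starch.
#' @param starch_uniform uniform starch level over the annulus (added to the
#'   gradient term).
#' @param mfa_outer,mfa_inner microfibril angle (degrees, in `[0, 90]`) at
#'   the outer / inner rim.
#' @param attenuation_scale linear attenuation per unit concentration per
#'   voxel.
#' @param seed unused placeholder for future stochastic microstructure; the
#'   phantom is deterministic.
#' @return object of class `tissue_phantom`: list of concentration maps
#'   (`cellulose`, `amorphous`, `starch`, `saxs`), `mfa_map`, `attenuation`,
#'   `voxel_size`, `support` (logical annulus mask).
#' @export
make_ring_phantom <- function(n_voxels = 64, voxel_size = 5,
                              outer_radius = 140, wall_thickness = 70,
                              wall_density = 1,
                              crystallinity_outer = 0.75,
                              crystallinity_inner = 0.35,
                              starch_gradient = 1, starch_uniform = 0,
                              mfa_outer = 5, mfa_inner = 30,
                              attenuation_scale = 0.02, seed = 0) {
  half_fov <- (n_voxels - 1) / 2 * voxel_size
  if (wall_thickness >= outer_radius)
    abort2("wall_thickness must be < outer_radius", "scatomo_config_error")
  if (outer_radius > half_fov)
    abort2("annulus exceeds the inscribed circle of the grid",
           "scatomo_config_error")
  if (any(c(mfa_outer, mfa_inner) < 0) || any(c(mfa_outer, mfa_inner) > 90))
    abort2("MFA must be in [0, 90] degrees", "scatomo_config_error")
  ctr <- (n_voxels + 1) / 2
  xy <- (seq_len(n_voxels) - ctr) * voxel_size
  R <- sqrt(outer(xy^2, xy^2, `+`))
  inner_radius <- outer_radius - wall_thickness
  support <- R <= outer_radius & R >= inner_radius
  # radial position u: 0 at outer rim, 1 at inner rim
  u <- (outer_radius - R) / wall_thickness
  u[!support] <- 0
  cf <- crystallinity_outer + (crystallinity_inner - crystallinity_outer) * u
  zero <- matrix(0, n_voxels, n_voxels)
  cellulose <- zero; amorphous <- zero; starch <- zero
  cellulose[support] <- wall_density * cf[support]
  amorphous[support] <- wall_density * (1 - cf[support])
  # quadratic rise toward the inner periphery: starch accumulates in the
  # innermost tissue and its profile is not collinear with the wall gradients
  starch[support] <- starch_uniform + starch_gradient * u[support]^2
  saxs <- cellulose * 0.5  # fibril correlation follows the cellulose
  mfa_map <- zero
  mfa_map[support] <- mfa_outer + (mfa_inner - mfa_outer) * u[support]
  total <- cellulose + amorphous + starch + saxs
  structure(list(
    concentration = list(cellulose = cellulose, amorphous = amorphous,
                         starch = starch, saxs = saxs),
    mfa_map = mfa_map,
    attenuation = attenuation_scale * total,
    voxel_size = voxel_size, support = support,
    geometry = list(outer_radius = outer_radius, inner_radius = inner_radius,
                    wall_density = wall_density)),
    class = "tissue_phantom")
}

#' Separable multi-blob validation phantom
#'
#' Three (or more) disjoint circular tissue domains, one per component,
#' placed symmetrically inside the inscribed circle. Because many beam paths
#' cross a single domain only, the simulated scan contains frames dominated
#' by each single component -- the near-separability condition under which
#' NMF can actually identify the underlying spectra and concentration maps.
#' (In an enclosing-wall geometry such as [make_ring_phantom()], every ray
#' mixes wall components and NMF recovers extreme mixtures instead; see the
#' package vignette.) Intended for decomposition validation.
#'
#' @param n_voxels grid side length.
#' @param voxel_size voxel edge, micrometre.
#' @param components names of the component maps to create (one blob each).
#' @param densities per-blob concentration (recycled).
#' @param blob_radius_frac blob radius as a fraction of the inscribed-circle
#'   radius (default 0.28).
#' @param ring_frac blob-center distance from the grid center as a fraction
#'   of the inscribed-circle radius (default 0.55).
#' @param mfa constant microfibril angle over all blobs, degrees.
#' @param attenuation_scale linear attenuation per unit concentration.
#' @return a `tissue_phantom` (see [make_ring_phantom()]).
#' @export
make_blob_phantom <- function(n_voxels = 48, voxel_size = 5,
                              components = c("cellulose", "amorphous", "starch"),
                              densities = 1, blob_radius_frac = 0.28,
                              ring_frac = 0.55, mfa = 20,
                              attenuation_scale = 0.02) {
  k <- length(components)
  densities <- rep_len(densities, k)
  ctr <- (n_voxels + 1) / 2
  rmax <- (n_voxels - 1) / 2
  rb <- blob_radius_frac * rmax
  rc <- ring_frac * rmax
  if (rc + rb > rmax)
    abort2("blobs exceed the inscribed circle", "scatomo_config_error")
  xg <- seq_len(n_voxels) - ctr
  conc <- list()
  total <- matrix(0, n_voxels, n_voxels)
  for (j in seq_len(k)) {
    th <- 2 * pi * (j - 1) / k
    cxy <- c(rc * cos(th), rc * sin(th))
    d2 <- outer((xg - cxy[2])^2, (xg - cxy[1])^2, `+`)
    m <- matrix(0, n_voxels, n_voxels)
    m[d2 <= rb^2] <- densities[j]
    conc[[components[j]]] <- m
    total <- total + m
  }
  mfa_map <- matrix(0, n_voxels, n_voxels)
  mfa_map[total > 0] <- mfa
  structure(list(
    concentration = conc, mfa_map = mfa_map,
    attenuation = attenuation_scale * total,
    voxel_size = voxel_size, support = total > 0,
    geometry = list(blob_radius = rb * voxel_size,
                    ring_radius = rc * voxel_size)),
    class = "tissue_phantom")
}

#' Acquisition configuration for a tomographic scan
#'
#' @param angles projection angles R_y, degrees in `[0, 180]`; default the
#'   half rotation at 1.5-degree intervals (121 angles).
#' @param x_step translation step, micrometre.
#' @param energy photon energy, keV.
#' @param photon_scale expected-counts scale for Poisson noise; `0` disables
#'   noise (deterministic frames).
#' @param seed RNG seed for the noise.
#' @param ordering `"sequential"` or `"interleaved"`; interleaved acquisition
#'   visits `n_groups` evenly spaced angle subsets in turn (each covering the
#'   half rotation), the scheme used to spread dose in time.
#' @param n_groups number of interleaved groups (default 8).
#' @param damage_rate optional per-frame multiplicative intensity decay
#'   `(1 - damage_rate)^frame_time_index`, a minimal radiation-damage model.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(angles = seq(0, 180, by = 1.5), x_step = 5,
                               energy = 15, photon_scale = 0, seed = 0,
                               ordering = c("sequential", "interleaved"),
                               n_groups = 8, damage_rate = 0) {
  ordering <- match.arg(ordering)
  if (any(angles < 0) || any(angles > 180))
    abort2("angles must be within [0, 180]", "scatomo_config_error")
  if (x_step <= 0) abort2("x_step must be > 0", "scatomo_config_error")
  if (photon_scale < 0) abort2("photon_scale must be >= 0", "scatomo_config_error")
  structure(list(angles = as.numeric(angles), x_step = x_step, energy = energy,
                 photon_scale = photon_scale, seed = seed, ordering = ordering,
                 n_groups = n_groups, damage_rate = damage_rate),
            class = "acquisition_config")
}

#' Acquisition-order permutation for interleaved angle groups
#'
#' Returns the order in which the (ascending) angle indices are visited:
#' group 1 first (indices 1, 1+g, 1+2g, ...), then group 2, and so on, each
#' group covering the half rotation with evenly spaced angles.
#'
#' @param n_angles number of projection angles.
#' @param n_groups number of groups.
#' @return integer permutation of `seq_len(n_angles)`.
#' @export
interleave_order <- function(n_angles, n_groups = 8) {
  as.integer(unlist(lapply(seq_len(n_groups),
                           function(g) seq(g, n_angles, by = n_groups))))
}

# per-voxel azimuthal envelope matrix G[voxel, phi]: Gaussian pair at +/-MFA,
# normalized to unit mean over the phi grid (so I_o is MFA-invariant)
.azim_envelope <- function(mfa_vec, phi_grid, sigma = 5) {
  G <- outer(mfa_vec, phi_grid, function(m, p)
    exp(-0.5 * ((p - m) / sigma)^2) + exp(-0.5 * ((p + m) / sigma)^2))
  G / rowMeans(G)
}

#' Forward-simulate a tomographic scattering scan
#'
#' For every projection angle the phantom's concentration maps (and
#' attenuation) are line-integrated along the beam via the Radon transform;
#' each frame's q-phi intensity is the sum over components of the projected
#' amount times the component spectrum times its azimuthal envelope
#' (voxel-additive for equatorial components, flat for isotropic ones). The
#' transmitted monitor is `exp(-` attenuation line integral `)`. Optional
#' Poisson noise at `photon_scale` counts per intensity unit and geometric
#' per-frame damage decay follow the acquisition ordering.
#'
#' @param phantom a [make_ring_phantom()] result (or any `tissue_phantom`).
#' @param components list of [component_spectrum()], all on one `q_grid`, with
#'   names matching `phantom$concentration`.
#' @param acquisition an [acquisition_config()].
#' @param phi_grid azimuthal grid, degrees (default 1-degree steps over
#'   `[-90, 90]`; central symmetry assumed already applied).
#' @param mfa_sigma intrinsic azimuthal width (Gaussian sigma) of equatorial
#'   reflections, degrees; 5 by default, matching the MFA analysis basis.
#' @param store `"frames"` keeps the full `[n_angle, n_x, n_q, n_phi]`
#'   intensity array; `"profiles"` keeps only the azimuthally integrated
#'   profiles `I_o` (sufficient for feature maps, NMF and clustering, and much
#'   smaller).
#' @return object of class `scan_set`: grids, monitors, acquisition order, and
#'   either `frames` (4-D array) or `profiles` (`[n_angle, n_x, n_q]`).
#' @export
simulate_scan <- function(phantom, components, acquisition = acquisition_config(),
                          phi_grid = seq(-90, 90, by = 1), mfa_sigma = 5,
                          store = c("frames", "profiles")) {
  store <- match.arg(store)
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(acquisition, "acquisition_config"))
  qg <- components[[1]]$q_grid
  for (cm in components)
    if (!isTRUE(all.equal(cm$q_grid, qg)))
      abort2("components must share one q_grid", "scatomo_grid_error")
  if (!all(names(components) %in% names(phantom$concentration)))
    abort2("component names must match phantom concentration maps",
           "scatomo_config_error")
  n <- nrow(phantom$mfa_map)
  angles <- acquisition$angles
  n_ang <- length(angles); n_q <- length(qg); n_phi <- length(phi_grid)
  A <- radon_matrix(n, angles, center = (n + 1) / 2)

  # projected attenuation -> transmission monitors
  att_proj <- t(matrix(as.numeric(A %*% as.vector(phantom$attenuation)), n))
  it <- exp(-att_proj)                 # [n_ang, n_x]
  i0 <- matrix(1, n_ang, n)

  # per-component projections
  iso_sino <- list(); eq_sino <- list()
  for (nm in names(components)) {
    conc <- phantom$concentration[[nm]]
    if (components[[nm]]$azimuthal_class == "isotropic") {
      iso_sino[[nm]] <- t(matrix(as.numeric(A %*% as.vector(conc)), n))
    } else {
      # voxel-additive azimuthal emission: project conc * G(phi; mfa) per phi
      G <- .azim_envelope(as.vector(phantom$mfa_map), phi_grid, mfa_sigma)
      W <- as.vector(conc) * G                      # [n^2, n_phi]
      P <- as.matrix(A %*% W)                       # [n_ang*n_x, n_phi]
      eq_sino[[nm]] <- array(P, c(n, n_ang, n_phi)) # x fastest within angle
    }
  }

  # time index per (angle, x) frame under the acquisition ordering; the x scan
  # runs fastest, angles in acquisition order
  acq <- if (acquisition$ordering == "interleaved")
    interleave_order(n_ang, acquisition$n_groups) else seq_len(n_ang)
  time_index <- matrix(0L, n_ang, n)
  for (k in seq_len(n_ang)) time_index[acq[k], ] <- (k - 1L) * n + seq_len(n) - 1L
  decay <- (1 - acquisition$damage_rate)^time_index

  if (acquisition$photon_scale > 0) set.seed(acquisition$seed)

  frames <- if (store == "frames") array(0, c(n_ang, n, n_q, n_phi)) else NULL
  profiles <- array(0, c(n_ang, n, n_q))
  spectra <- vapply(components, function(cm) cm$intensity, numeric(n_q))

  for (a in seq_len(n_ang)) {
    block <- array(0, c(n, n_q, n_phi))   # [x, q, phi]
    for (nm in names(iso_sino)) {
      amt <- iso_sino[[nm]][a, ]
      block <- block + outer(outer(amt, spectra[, nm]), rep(1, n_phi))
    }
    for (nm in names(eq_sino)) {
      Pphi <- eq_sino[[nm]][, a, ]        # [n_x, n_phi]
      block <- block + aperm(outer(Pphi, spectra[, nm]), c(1, 3, 2))
    }
    # measured intensity is attenuated by transmission and damage decay
    scale_ax <- it[a, ] * decay[a, ]
    block <- block * scale_ax             # recycles over x (first dim)
    if (acquisition$photon_scale > 0) {
      lam <- block * acquisition$photon_scale
      block <- array(rpois(length(lam), lam), dim(lam)) / acquisition$photon_scale
    }
    if (store == "frames") frames[a, , , ] <- block
    profiles[a, , ] <- 180 * apply(block, c(1, 2), mean)
  }

  structure(list(
    frames = frames, profiles = profiles,
    q_grid = qg, phi_grid = phi_grid, angles = angles,
    x_grid = (seq_len(n) - (n + 1) / 2) * acquisition$x_step,
    i0 = i0, it = it, acq_order = acq, time_index = time_index,
    acquisition = acquisition, mfa_sigma = mfa_sigma,
    components = names(components), voxel_size = phantom$voxel_size),
    class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d angles x %d positions, %d q bins, %d phi bins (%s)\n",
              length(x$angles), length(x$x_grid), length(x$q_grid),
              length(x$phi_grid),
              if (is.null(x$frames)) "profiles only" else "full frames"))
  invisible(x)
}

#' Extract one frame of a scan as a q-phi map
#'
#' @param scan a `scan_set` simulated (or loaded) with `store = "frames"`.
#' @param i_angle,i_x indices into the angle and translation grids.
#' @return a [qphi_map()] with the frame's monitors.
#' @export
get_frame <- function(scan, i_angle, i_x) {
  stopifnot(inherits(scan, "scan_set"))
  if (is.null(scan$frames))
    abort2("scan was stored without full frames", "scatomo_data_error")
  qphi_map(scan$frames[i_angle, i_x, , ], scan$q_grid, scan$phi_grid,
           i0 = scan$i0[i_angle, i_x], it = scan$it[i_angle, i_x])
}

#' Azimuthally integrated profiles of every frame
#'
#' @param scan a `scan_set`.
#' @return array `[n_angle, n_x, n_q]` of I_o profiles.
#' @export
scan_profiles <- function(scan) {
  stopifnot(inherits(scan, "scan_set"))
  scan$profiles
}
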