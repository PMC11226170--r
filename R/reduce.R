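# Per-frame reduction: q/angle conversion, azimuthal integration, background
# and absorption correction, rolling-ball despiking, q-smearing estimate.

#' Construct a q-phi intensity map
#'
#' The unit record of a scan: scattering intensity on a fixed grid of momentum
#' transfer q (rows) and azimuthal angle phi (columns), together with the
#' incident (`i0`) and transmitted (`it`) monitor readings for the frame.
#'
#' @param intensity numeric matrix `[n_q, n_phi]`, non-negative.
#' @param q_grid strictly increasing q values, inverse Angstrom.
#' @param phi_grid strictly increasing azimuthal angles, degrees in
#'   `[-90, 90]`; `phi = 0` is the equator of the fiber-diffraction diagram.
#' @param i0,it incident and transmitted monitor values; `0 < it <= i0`.
#' @param mask optional logical matrix, `TRUE` where the bin is valid.
#' @return object of class `qphi_map`.
#' @export
qphi_map <- function(intensity, q_grid, phi_grid, i0 = 1, it = 1, mask = NULL) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(q_grid) || ncol(intensity) != length(phi_grid))
    abort2("intensity must be [n_q, n_phi]", "scatomo_grid_error")
  if (any(diff(q_grid) <= 0) || (length(phi_grid) > 1 && any(diff(phi_grid) <= 0)))
    abort2("grids must be strictly increasing", "scatomo_grid_error")
  if (i0 <= 0 || it <= 0 || it > i0 * (1 + 1e-12))
    abort2("monitors must satisfy 0 < it <= i0", "scatomo_monitor_error")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopifnot(all(dim(mask) == dim(intensity)))
  }
  structure(list(intensity = intensity, q_grid = as.numeric(q_grid),
                 phi_grid = as.numeric(phi_grid), i0 = i0, it = it, mask = mask),
            class = "qphi_map")
}

#' Construct a 1-D scattering profile
#'
#' @param q_grid momentum transfer, inverse Angstrom.
#' @param intensity intensity values, arbitrary units.
#' @param sigma optional pointwise uncertainties (>= 0).
#' @return object of class `profile1d`.
#' @export
profile1d <- function(q_grid, intensity, sigma = NULL) {
  if (length(q_grid) != length(intensity))
    abort2("q_grid and intensity lengths differ", "scatomo_grid_error")
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(intensity), all(sigma >= 0, na.rm = TRUE))
  }
  structure(list(q_grid = as.numeric(q_grid), intensity = as.numeric(intensity),
                 sigma = sigma), class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %d points, q in [%.3g, %.3g] 1/A\n",
              length(x$q_grid), min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' Momentum transfer from scattering angle
#'
#' `q = 4 pi sin(theta) / lambda` with `2 theta` the scattering angle and
#' `lambda = 12.3984 / energy` the X-ray wavelength in Angstrom.
#'
#' @param twotheta scattering angle 2-theta, degrees, in `[0, 180)`.
#' @param energy photon energy, keV.
#' @return momentum transfer, inverse Angstrom.
#' @examples
#' q_from_angle(15.2, 8)  # ~1.07 1/A, the first A-type starch peak
#' @export
q_from_angle <- function(twotheta, energy) {
  if (any(twotheta < 0) || any(twotheta >= 180))
    abort2("twotheta must be in [0, 180)", "scatomo_range_error")
  if (any(energy <= 0)) abort2("energy must be positive", "scatomo_range_error")
  lambda <- HC_KEV_A / energy
  4 * pi * sin(twotheta / 2 * pi / 180) / lambda
}

#' Scattering angle from momentum transfer
#'
#' Inverse of [q_from_angle()].
#'
#' @param q momentum transfer, inverse Angstrom; must satisfy
#'   `q * lambda / (4 pi) <= 1`.
#' @param energy photon energy, keV.
#' @return scattering angle 2-theta, degrees.
#' @export
angle_from_q <- function(q, energy) {
  if (any(q < 0)) abort2("q must be non-negative", "scatomo_range_error")
  lambda <- HC_KEV_A / energy
  s <- q * lambda / (4 * pi)
  if (any(s > 1)) abort2("q is unphysical at this energy", "scatomo_range_error")
  2 * asin(s) * 180 / pi
}

#' Azimuthally integrated intensity profile I_o(q)
#'
#' Mask-aware mean over phi multiplied by the full azimuthal range (180
#' degrees), so a uniform map of value c gives 180 * c at every q. Equivalent
#' to the powder-average profile used as the rotation-invariant basis for
#' tomographic reconstruction. Fully masked q rows are returned as `NA`.
#'
#' @param map a [qphi_map()].
#' @return a [profile1d()].
#' @export
azimuthal_average <- function(map) {
  stopifnot(inherits(map, "qphi_map"))
  intens <- map$intensity
  if (!is.null(map$mask)) {
    intens[!map$mask] <- NA_real_
  }
  m <- rowMeans(intens, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  profile1d(map$q_grid, 180 * m)
}

#' Equatorial intensity profile I_e(q)
#'
#' Mean intensity over the azimuthal band `|phi| <= half_width`, the profile
#' on the equator of the fiber-diffraction diagram. Appropriate when the
#' cellulose peak is unsplit (near-zero microfibril angle).
#'
#' @param map a [qphi_map()].
#' @param half_width half-width of the equatorial band, degrees. `0` selects
#'   the bin(s) nearest phi = 0.
#' @return a [profile1d()].
#' @export
equatorial_profile <- function(map, half_width = 5) {
  stopifnot(inherits(map, "qphi_map"), half_width >= 0)
  sel <- abs(map$phi_grid) <= half_width
  if (!any(sel)) sel <- abs(map$phi_grid) == min(abs(map$phi_grid))
  intens <- map$intensity
  if (!is.null(map$mask)) intens[!map$mask] <- NA_real_
  profile1d(map$q_grid, rowMeans(intens[, sel, drop = FALSE], na.rm = TRUE))
}

#' Background subtraction and absorption correction
#'
#' Subtracts the (empty-beam) background scaled by the frame's transmitted
#' intensity and divides by the transmission `T = it / i0`, so the corrected
#' intensity is proportional to scattering per unit illuminated material:
#' `I_corr = (I - T * (i0 / i0_bg) * I_bg) / T`. Negative results are clipped
#' at zero; the number of clipped bins is recorded in attribute `n_clipped`.
#'
#' @param map a [qphi_map()].
#' @param background a [profile1d()] (isotropic, broadcast over phi) or a
#'   [qphi_map()] on the same grids.
#' @param i0_bg incident monitor under which the background was recorded.
#' @return corrected [qphi_map()] with attribute `n_clipped`.
#' @export
correct_frame <- function(map, background, i0_bg = 1) {
  stopifnot(inherits(map, "qphi_map"))
  tr <- map$it / map$i0
  if (tr <= 0) abort2("non-positive transmission", "scatomo_monitor_error")
  if (inherits(background, "profile1d")) {
    if (length(background$q_grid) != length(map$q_grid))
      abort2("background q grid mismatch", "scatomo_grid_error")
    bg <- matrix(background$intensity, nrow = length(map$q_grid),
                 ncol = length(map$phi_grid))
  } else if (inherits(background, "qphi_map")) {
    if (!isTRUE(all.equal(background$q_grid, map$q_grid)) ||
        !isTRUE(all.equal(background$phi_grid, map$phi_grid)))
      abort2("background grids mismatch", "scatomo_grid_error")
    bg <- background$intensity
  } else abort2("background must be profile1d or qphi_map", "scatomo_type_error")
  corr <- (map$intensity - tr * (map$i0 / i0_bg) * bg) / tr
  n_clip <- sum(corr < 0)
  corr[corr < 0] <- 0
  out <- qphi_map(corr, map$q_grid, map$phi_grid, i0 = map$i0, it = map$it,
                  mask = map$mask)
  attr(out, "n_clipped") <- n_clip
  out
}

# Running minimum / maximum with window 2*radius + 1. The signal is padded by
# linear extrapolation of the boundary slope so the opening preserves smooth
# monotone profiles up to the edges (plain replication flattens the last
# `radius` bins of a ramp); any extrapolation overshoot is clamped later.
.run_extreme <- function(x, radius, fun) {
  n <- length(x)
  lo <- x[1] - seq(radius, 1) * (x[2] - x[1])
  hi <- x[n] + seq_len(radius) * (x[n] - x[n - 1])
  pad <- c(lo, x, hi)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- fun(pad[i:(i + 2 * radius)])
  out
}

#' Rolling-ball baseline and despiking of a 1-D profile
#'
#' Grey-scale opening (minimum filter followed by maximum filter, window
#' `2 * radius + 1` bins) estimates a baseline that passes under broad
#' features but excludes sharp ones. Spikes are then suppressed by clamping
#' the profile at `baseline + k_sigma * MAD(profile - baseline)`. Used both to
#' remove sharp cuticular-wax diffraction spikes and to estimate the baseline
#' under narrow starch peaks.
#'
#' @param profile a [profile1d()].
#' @param radius structuring-element radius in q bins; features narrower than
#'   the window are excluded from the baseline.
#' @param k_sigma spike threshold in robust sigma units (default 5).
#' @return list with elements `baseline` and `despiked`, both [profile1d()].
#' @export
rolling_ball <- function(profile, radius = 8, k_sigma = 5) {
  stopifnot(inherits(profile, "profile1d"))
  n <- length(profile$intensity)
  if (radius < 1) abort2("radius must be >= 1", "scatomo_range_error")
  if (2 * radius + 1 > n)
    abort2("radius too large for profile length", "scatomo_range_error")
  x <- profile$intensity
  base <- .run_extreme(.run_extreme(x, radius, min), radius, max)
  base <- pmin(base, x)  # opening is <= profile; guard edge padding
  resid <- x - base
  thr <- base + k_sigma * mad(resid, center = 0)
  despiked <- pmin(x, thr)
  list(baseline = profile1d(profile$q_grid, base),
       despiked = profile1d(profile$q_grid, despiked))
}

#' Geometric q-smearing estimate
#'
#' Different parts of a laterally extended sample scatter into the same
#' detector pixel at slightly different q. The relative q uncertainty is
#' `sample_extent / detector_distance`, and the absolute smearing at a peak
#' position is that fraction times the peak q.
#'
#' @param sample_extent maximum lateral sample dimension, mm.
#' @param detector_distance sample-to-detector distance, mm.
#' @param q_peak q at which to evaluate the absolute smearing, inverse
#'   Angstrom (e.g. the cellulose main peak at ~1.6).
#' @return list with `relative` (fraction) and `absolute` (inverse Angstrom).
#' @examples
#' q_smearing(5, 350, 1.6)  # ~1.5% relative, ~0.02 1/A
#' @export
q_smearing <- function(sample_extent, detector_distance, q_peak) {
  if (detector_distance <= 0 || sample_extent < 0)
    abort2("distances must be positive", "scatomo_range_error")
  rel <- sample_extent / detector_distance
  list(relative = rel, absolute = rel * q_peak)
}

#' Absorption-correct (and background-subtract) a whole scan
#'
#' Applies the per-frame correction of [correct_frame()] to every frame of a
#' scan: the optional isotropic background is subtracted scaled by each
#' frame's transmission, and the intensity is divided by `T = it / i0`.
#' After correction the azimuthally integrated intensity is proportional to
#' material per illuminated path and its sum over x is angle-independent --
#' the precondition for feature tomography.
#'
#' @param scan a `scan_set`.
#' @param background optional [profile1d()] on the scan's q grid (an
#'   empty-beam I_o background); subtraction acts on the stored profiles and,
#'   when present, frames (assumed isotropic, i.e. divided by 180 over phi).
#' @param i0_bg incident monitor of the background measurement.
#' @return the corrected `scan_set` (monitors reset so `it = i0`; attribute
#'   `n_clipped` counts negative bins clipped to zero).
#' @export
correct_scan <- function(scan, background = NULL, i0_bg = 1) {
  stopifnot(inherits(scan, "scan_set"))
  tr <- scan$it / scan$i0
  if (any(tr <= 0)) abort2("non-positive transmission", "scatomo_monitor_error")
  n_ang <- dim(scan$profiles)[1]; n_x <- dim(scan$profiles)[2]
  bg <- if (is.null(background)) 0 else {
    if (length(background$q_grid) != length(scan$q_grid))
      abort2("background q grid mismatch", "scatomo_grid_error")
    background$intensity
  }
  n_clip <- 0
  for (a in seq_len(n_ang)) for (x in seq_len(n_x)) {
    p <- (scan$profiles[a, x, ] - tr[a, x] * (scan$i0[a, x] / i0_bg) * bg) /
      tr[a, x]
    n_clip <- n_clip + sum(p < 0)
    scan$profiles[a, x, ] <- pmax(p, 0)
    if (!is.null(scan$frames)) {
      f <- (scan$frames[a, x, , ] -
              tr[a, x] * (scan$i0[a, x] / i0_bg) * bg / 180) / tr[a, x]
      scan$frames[a, x, , ] <- pmax(f, 0)
    }
  }
  scan$absorption <- -log(tr)
  scan$it <- scan$i0
  attr(scan, "n_clipped") <- n_clip
  scan
}

#' Low-intensity background estimate from a scan
#'
#' Averages the azimuthally integrated profiles of the frames with the lowest
#' total intensity (the translations where the beam misses the sample),
#' giving an empty-beam background for [correct_scan()].
#'
#' @param scan a `scan_set`.
#' @param fraction fraction of lowest-total frames to average (default 0.01,
#'   at least one frame).
#' @return a [profile1d()].
#' @export
estimate_background <- function(scan, fraction = 0.01) {
  stopifnot(inherits(scan, "scan_set"))
  prof <- scan_profiles(scan)
  n_frames <- dim(prof)[1] * dim(prof)[2]
  X <- matrix(aperm(prof, c(2, 1, 3)), n_frames, dim(prof)[3])
  tot <- rowSums(X)
  k <- max(1L, floor(fraction * n_frames))
  sel <- order(tot)[seq_len(k)]
  profile1d(scan$q_grid, colMeans(X[sel, , drop = FALSE]))
}

#' Export a profile as 3-column text
#'
#' Writes `q`, intensity and (if present) sigma as whitespace-separated text.
#'
#' @param profile a [profile1d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile1d"))
  sig <- profile$sigma %||% rep(0, length(profile$q_grid))
  df <- data.frame(q = profile$q_grid, I = profile$intensity, sigma = sig)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
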