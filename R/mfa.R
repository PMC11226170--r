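# Microfibril-angle analysis: projection-averaged azimuthal profiles,
# amorphous subtraction, discrete-MFA basis, regularized NNLS, nominal MFA
# and per-voxel azimuthal reconstruction.

#' Construct an azimuthal intensity profile
#'
#' @param phi_grid azimuthal angles, degrees, symmetric about 0.
#' @param intensity non-negative intensities.
#' @return object of class `azim_profile`.
#' @export
azim_profile <- function(phi_grid, intensity) {
  if (length(phi_grid) != length(intensity))
    abort2("grid/intensity length mismatch", "scatomo_grid_error")
  if (max(abs(phi_grid + rev(phi_grid))) > 1e-6)
    abort2("phi grid must be symmetric about 0", "scatomo_grid_error")
  structure(list(phi_grid = as.numeric(phi_grid),
                 intensity = as.numeric(intensity)), class = "azim_profile")
}

# q-window azimuthal profile of a [n_q, n_phi] block, baseline-subtracted:
# integrate the peak window over q, subtract the width-scaled baseline-window
# integral per phi, clip at zero
.azim_window_profile <- function(intens, q_grid, peak_window, baseline_window) {
  sel_p <- .window_sel(q_grid, peak_window[1], peak_window[2])
  peak <- apply(intens[sel_p, , drop = FALSE], 2, function(col)
    pracma::trapz(q_grid[sel_p], col))
  if (is.null(baseline_window)) return(pmax(peak, 0))
  sel_b <- .window_sel(q_grid, baseline_window[1], baseline_window[2])
  base <- apply(intens[sel_b, , drop = FALSE], 2, function(col)
    pracma::trapz(q_grid[sel_b], col))
  w_p <- diff(range(q_grid[sel_p])); w_b <- diff(range(q_grid[sel_b]))
  pmax(peak - base * w_p / w_b, 0)
}

#' Projection-averaged azimuthal profile of the cellulose peak
#'
#' Averaging the scattering over all projection angles makes every cell-wall
#' orientation contribute equally, so the azimuthal shape of the averaged
#' cellulose reflection reflects the whole-sample MFA distribution alone. The
#' q-phi intensity is averaged over all frames, integrated over the
#' crystalline-cellulose peak window, and the isotropic (amorphous)
#' contribution -- estimated from the intensity just outside the peak,
#' q = 1.8-1.9 1/A by default, scaled by the window widths -- is subtracted
#' per phi and the result clipped at zero.
#'
#' @param scan a `scan_set` with full frames.
#' @param peak_window `c(qmin, qmax)` over the cellulose peak.
#' @param baseline_window `c(qmin, qmax)` outside the peak (default
#'   `c(1.8, 1.9)`); `NULL` skips the subtraction.
#' @return an [azim_profile()]. If the baseline exceeds the peak everywhere a
#'   warning is issued and the profile is all zero.
#' @export
projection_averaged_profile <- function(scan, peak_window,
                                        baseline_window = c(1.8, 1.9)) {
  stopifnot(inherits(scan, "scan_set"))
  if (is.null(scan$frames))
    abort2("scan was stored without full frames", "scatomo_data_error")
  mean_map <- apply(scan$frames, c(3, 4), mean)  # [n_q, n_phi]
  prof <- .azim_window_profile(mean_map, scan$q_grid, peak_window,
                               baseline_window)
  if (all(prof <= 0))
    warning("baseline exceeds peak intensity at all phi; profile is zero")
  azim_profile(scan$phi_grid, prof)
}

#' Discrete-MFA azimuthal basis matrix
#'
#' Column `j` is the azimuthal intensity distribution expected from
#' microfibrils at a single MFA value `mu_j`: a symmetric pair of Gaussians
#' centered at `+/- mu_j` with sigma equal to the intrinsic width (a single
#' peak at 0 for `mu = 0`), normalized to unit integral over phi.
#'
#' @param phi_grid azimuthal grid, degrees.
#' @param mfa_values discrete MFA values, degrees; default 0 to 90 in steps
#'   of 3 (31 values).
#' @param width intrinsic azimuthal peak width (Gaussian sigma), degrees,
#'   default 5.
#' @return object of class `mfa_basis`: `A` (`[n_phi, n_mfa]`, columns of
#'   unit integral), `mfa_values`, `phi_grid`, `width`.
#' @export
build_mfa_basis <- function(phi_grid, mfa_values = seq(0, 90, by = 3),
                            width = 5) {
  stopifnot(width > 0)
  A <- vapply(mfa_values, function(mu)
    exp(-0.5 * ((phi_grid - mu) / width)^2) +
      exp(-0.5 * ((phi_grid + mu) / width)^2), numeric(length(phi_grid)))
  dphi <- mean(diff(phi_grid))
  A <- sweep(A, 2, colSums(A) * dphi, `/`)
  structure(list(A = A, mfa_values = as.numeric(mfa_values),
                 phi_grid = as.numeric(phi_grid), width = width),
            class = "mfa_basis")
}

#' Non-negative least squares with ridge and smoothness regularization
#'
#' Solves `argmin_{x >= 0} |y - A x|^2 + lambda1 |I x|^2 + lambda2 |D x|^2`
#' where `D` is the first-difference operator (entries of -1 directly below
#' the diagonal), by stacking the augmented system
#' `[A; sqrt(lambda1) I; sqrt(lambda2) D]` against `[y; 0; 0]` and running
#' standard NNLS. The ridge term discourages over-fitting, the difference
#' term favors smooth MFA distributions.
#'
#' @param A basis matrix `[n_obs, n]` or an `mfa_basis`.
#' @param y observed profile (non-negative).
#' @param lambda1 ridge weight (default 0.01).
#' @param lambda2 smoothness weight (default 0.1).
#' @return object of class `mfa_distribution`: `weights` (`x >= 0`),
#'   `residual` (`|y - A x|` on the unaugmented system), `lambda1`, `lambda2`.
#' @export
nnls_regularized <- function(A, y, lambda1 = 0.01, lambda2 = 0.1) {
  basis <- NULL
  if (inherits(A, "mfa_basis")) { basis <- A; A <- basis$A }
  A <- as.matrix(A)
  if (length(y) != nrow(A))
    abort2("length(y) must equal nrow(A)", "scatomo_grid_error")
  if (lambda1 < 0 || lambda2 < 0)
    abort2("regularization weights must be >= 0", "scatomo_config_error")
  n <- ncol(A)
  D <- diag(n)
  if (n > 1) D[cbind(2:n, 1:(n - 1))] <- -1
  # solve on the max-normalized profile so the effective regularization
  # strength is independent of the intensity scale; weights scale back
  y_scale <- max(y)
  if (y_scale <= 0) y_scale <- 1
  Aaug <- rbind(A, sqrt(lambda1) * diag(n), sqrt(lambda2) * D)
  yaug <- c(y / y_scale, rep(0, 2 * n))
  x <- pracma::lsqnonneg(Aaug, yaug)$x * y_scale
  x[x < 0] <- 0
  structure(list(weights = x, residual = sqrt(sum((y - A %*% x)^2)),
                 lambda1 = lambda1, lambda2 = lambda2,
                 mfa_values = basis$mfa_values),
            class = "mfa_distribution")
}

#' Nominal microfibril angle of an azimuthal profile
#'
#' The intensity-weighted average of the absolute azimuthal position:
#' `phi_a = sum(|phi_i| I(phi_i)) / sum(I(phi_i))`. Not a direct MFA
#' measurement, but `phi_a = 0` when all microfibrils align with the growth
#' direction, and small MFAs give small `phi_a`. Scale-invariant in the
#' intensity.
#'
#' @param profile an [azim_profile()] (or list with `phi_grid`, `intensity`).
#' @return `phi_a` in degrees, or `NA` for zero total intensity.
#' @export
nominal_mfa <- function(profile) {
  tot <- sum(profile$intensity)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(abs(profile$phi_grid) * profile$intensity) / tot
}

#' Per-azimuthal-bin tomogram stack
#'
#' Builds one sinogram per azimuthal bin from the cellulose-peak window
#' (optionally after per-phi subtraction of the isotropic baseline window)
#' and reconstructs each, yielding the azimuthal intensity profile of every
#' voxel, `I(phi; y, x)`. All reconstructions reuse one rotation center. The
#' phi grid may be coarsened by `phi_bin` for speed.
#'
#' @param scan a `scan_set` with full frames.
#' @param peak_window `c(qmin, qmax)` over the cellulose peak.
#' @param baseline_window isotropic-baseline window or `NULL`.
#' @param algorithm `"fbp"` (fast, negatives clipped) or `"mlem"`/`"sirt"`.
#' @param n_iter iterations for iterative algorithms.
#' @param center shared rotation center (default geometric).
#' @param phi_bin bin width in phi samples (default 1 = no binning).
#' @return object of class `phi_stack`: `values` array `[n_y, n_x, n_phi]`
#'   (non-negative), `phi_grid`, `voxel_size`.
#' @export
per_phi_tomograms <- function(scan, peak_window, baseline_window = c(1.8, 1.9),
                              algorithm = c("fbp", "mlem", "sirt"),
                              n_iter = 100, center = NULL, phi_bin = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(scan, "scan_set"))
  if (is.null(scan$frames))
    abort2("scan was stored without full frames", "scatomo_data_error")
  n_ang <- length(scan$angles); n_x <- length(scan$x_grid)
  phi <- scan$phi_grid
  if (phi_bin > 1) {
    groups <- split(seq_along(phi), ceiling(seq_along(phi) / phi_bin))
  } else {
    groups <- as.list(seq_along(phi))
  }
  phi_out <- vapply(groups, function(g) mean(phi[g]), numeric(1))
  n <- n_x
  if (is.null(center)) center <- (n + 1) / 2
  ord <- order(scan$angles)
  # per-frame baseline-subtracted azimuthal profiles of the peak window
  prof_phi <- array(0, c(n_ang, n_x, length(phi)))
  for (a in seq_len(n_ang)) for (x in seq_len(n_x)) {
    prof_phi[a, x, ] <- .azim_window_profile(scan$frames[a, x, , ],
                                             scan$q_grid, peak_window,
                                             baseline_window)
  }
  stack <- array(0, c(n, n, length(groups)))
  for (g in seq_along(groups)) {
    vals <- apply(prof_phi[, , groups[[g]], drop = FALSE], c(1, 2), mean)
    sino <- sinogram(vals[ord, , drop = FALSE], angles = scan$angles[ord],
                     x_grid = scan$x_grid, feature = "per_phi")
    tomo <- switch(algorithm,
      fbp = fbp(sino, center = center, clip_negative = TRUE),
      iterative_recon(sino, algorithm = algorithm, n_iter = n_iter,
                      center = center))
    stack[, , g] <- tomo$values
  }
  structure(list(values = stack, phi_grid = phi_out,
                 voxel_size = scan$voxel_size), class = "phi_stack")
}

#' Per-voxel nominal-MFA map and MFA distributions
#'
#' For every voxel whose total azimuthal intensity is at least `min_frac` of
#' the maximum voxel total, computes the nominal MFA `phi_a` and (optionally)
#' the full regularized-NNLS MFA distribution. Masked voxels get `NA` and no
#' distribution.
#'
#' @param stack a [per_phi_tomograms()] result.
#' @param basis an [build_mfa_basis()] result on the stack's phi grid.
#' @param lambda1,lambda2 regularization weights for [nnls_regularized()].
#' @param min_frac masking threshold (fraction of max voxel total, default
#'   0.05).
#' @param distributions if `FALSE`, skip the per-voxel NNLS (the `phi_a` map
#'   alone is much faster).
#' @return list with `phi_a` ([tomogram()], degrees, `NA` where masked),
#'   `distributions` (`[n_voxel_valid, n_mfa]` weight matrix or `NULL`),
#'   `valid` (logical matrix), `mfa_values`.
#' @export
mfa_maps <- function(stack, basis, lambda1 = 0.01, lambda2 = 0.1,
                     min_frac = 0.05, distributions = TRUE) {
  stopifnot(inherits(stack, "phi_stack"), inherits(basis, "mfa_basis"))
  if (length(basis$phi_grid) != length(stack$phi_grid) ||
      max(abs(basis$phi_grid - stack$phi_grid)) > 1e-6)
    abort2("basis and stack phi grids differ", "scatomo_grid_error")
  dims <- dim(stack$values)[1:2]
  n_phi <- dim(stack$values)[3]
  V <- matrix(stack$values, prod(dims), n_phi)  # voxel-major
  tot <- rowSums(V)
  valid <- tot >= min_frac * max(tot) & tot > 0
  phi_abs <- abs(stack$phi_grid)
  phi_a <- rep(NA_real_, prod(dims))
  phi_a[valid] <- (V[valid, , drop = FALSE] %*% phi_abs) / tot[valid]
  dist <- NULL
  if (distributions) {
    idx <- which(valid)
    dist <- matrix(0, length(idx), length(basis$mfa_values))
    for (i in seq_along(idx)) {
      fit <- nnls_regularized(basis, V[idx[i], ], lambda1, lambda2)
      dist[i, ] <- fit$weights
    }
  }
  list(phi_a = tomogram(matrix(phi_a, dims[1], dims[2]),
                        voxel_size = stack$voxel_size, feature = "phi_a",
                        mask = matrix(valid, dims[1], dims[2])),
       distributions = dist, valid = matrix(valid, dims[1], dims[2]),
       mfa_values = basis$mfa_values)
}

#' Earth-mover distance between two distributions on one grid
#'
#' One-dimensional Wasserstein-1 distance between normalized weight vectors
#' on a common (uniform) grid: the integral of the absolute difference of the
#' cumulative distributions.
#'
#' @param w1,w2 non-negative weight vectors (normalized internally).
#' @param grid common support grid (e.g. MFA values in degrees).
#' @return distance in grid units.
#' @export
emd_1d <- function(w1, w2, grid) {
  stopifnot(length(w1) == length(grid), length(w2) == length(grid))
  p <- w1 / sum(w1); q <- w2 / sum(w2)
  step <- mean(diff(grid))
  sum(abs(cumsum(p - q))) * step
}
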