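# Tomographic reconstruction on a shared sparse Radon system matrix.
#
# Geometry: image is n x n, pixel spacing 1 (scaled to voxel_size outside).
# At projection angle 0 the beam runs along image rows (integration over the
# row index) and the detector axis coincides with the column axis; rotation is
# counter-clockwise. Detector bin s and beam parameter t sample the plane at
# unit spacing; each sample point bilinearly interpolates the image, so the
# forward operator and its exact transpose (used for back-projection and the
# iterative algorithms) come from one matrix.

#' Construct a sinogram object
#'
#' @param values numeric matrix `[n_angles, n_x]` of a scalar feature per
#'   (projection angle, translation) pair.
#' @param angles projection angles R_y, degrees, ascending.
#' @param x_grid translation positions, micrometre.
#' @param feature label of the feature the sinogram is based on.
#' @param window optional `(qmin, qmax)` integration window, inverse Angstrom.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, angles, x_grid = seq_len(ncol(values)),
                     feature = "intensity", window = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(angles) || ncol(values) != length(x_grid))
    abort2("sinogram dims must match angles and x_grid", "scatomo_grid_error")
  if (any(!is.finite(values)))
    abort2("sinogram values must be finite", "scatomo_value_error")
  if (is.unsorted(angles))
    abort2("angles must be ascending (reorder interleaved groups first)",
           "scatomo_order_error")
  structure(list(values = values, angles = as.numeric(angles),
                 x_grid = as.numeric(x_grid), feature = feature,
                 window = window), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> feature '%s': %d angles x %d positions\n",
              x$feature, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a tomogram object
#'
#' @param values numeric matrix `[n_y, n_x]`, feature units per voxel.
#' @param voxel_size voxel edge length, micrometre.
#' @param feature label.
#' @param mask optional logical validity map (`FALSE` = excluded voxel).
#' @return object of class `tomogram`.
#' @export
tomogram <- function(values, voxel_size = 1, feature = "intensity", mask = NULL) {
  values <- as.matrix(values)
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(values)))
  structure(list(values = values, voxel_size = voxel_size, feature = feature,
                 mask = mask), class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  cat(sprintf("<tomogram> feature '%s': %d x %d voxels (%g um)\n",
              x$feature, nrow(x$values), ncol(x$values), x$voxel_size))
  invisible(x)
}

# Sparse projector rows for one angle; returns triplets. `oversample`
# refines the sampling step along the beam (weights scaled accordingly),
# which tightens angle-independence of the projection mass.
.projector_angle_triplets <- function(n, theta_deg, center, row0,
                                      oversample = 2) {
  th <- theta_deg * pi / 180
  s_rel <- seq_len(n) - center          # detector coordinate per ray
  t_rel <- seq(1, n, by = 1 / oversample) - (n + 1) / 2  # along the beam
  # sample coordinates relative to the rotation center
  X <- outer(s_rel, t_rel, function(s, t) s * cos(th) - t * sin(th))
  Y <- outer(s_rel, t_rel, function(s, t) s * sin(th) + t * cos(th))
  cx <- X + center
  cy <- Y + (n + 1) / 2
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0;   fy <- cy - r0
  ray <- row(X) + row0                  # A row index per sample
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in 1:4) {
    cc <- c0 + (k == 2 | k == 4)
    rr <- r0 + (k >= 3)
    w <- (if (k %% 2 == 1) 1 - fx else fx) * (if (k <= 2) 1 - fy else fy) /
      oversample
    ok <- cc >= 1 & cc <= n & rr >= 1 & rr <= n & w > 0
    ii <- c(ii, ray[ok]); jj <- c(jj, ((cc - 1) * n + rr)[ok]); ww <- c(ww, w[ok])
  }
  list(i = ii, j = jj, w = ww)
}

#' Sparse Radon system matrix
#'
#' Builds (and caches per geometry) the `(n_angles * n) x n^2` sparse matrix
#' whose rows are the line-integral weights of each (angle, detector bin) ray,
#' sampled at unit spacing with bilinear interpolation. The same matrix powers
#' [radon()], [fbp()] and [iterative_recon()], so forward and back projection
#' are exact transposes of each other.
#'
#' @param n image side length, pixels.
#' @param angles projection angles, degrees.
#' @param center rotation center, fractional detector pixels (1-based;
#'   default the geometric center `(n + 1) / 2`).
#' @param oversample sampling refinement along the beam (default 2).
#' @return a `dgCMatrix`.
#' @export
radon_matrix <- function(n, angles, center = (n + 1) / 2, oversample = 2) {
  key <- paste0("A_", n, "_", center, "_", oversample, "_",
                rlang::hash(as.numeric(angles)))
  cached <- .scatomo_env[[key]]
  if (!is.null(cached)) return(cached)
  tri_i <- vector("list", length(angles))
  tri_j <- vector("list", length(angles))
  tri_w <- vector("list", length(angles))
  for (a in seq_along(angles)) {
    tr <- .projector_angle_triplets(n, angles[a], center, row0 = (a - 1) * n,
                                    oversample = oversample)
    tri_i[[a]] <- tr$i; tri_j[[a]] <- tr$j; tri_w[[a]] <- tr$w
  }
  A <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                            x = unlist(tri_w),
                            dims = c(length(angles) * n, n * n))
  # keep at most a few geometries cached
  if (length(ls(.scatomo_env)) > 6) rm(list = ls(.scatomo_env), envir = .scatomo_env)
  .scatomo_env[[key]] <- A
  A
}

#' Radon transform (forward projection)
#'
#' Line integrals of a square image at the given projection angles. For an
#' object supported inside the inscribed circle of the grid, every row of the
#' result has the same total (the image mass), which is the precondition for
#' scalar scattering tomography.
#'
#' @param image square numeric matrix.
#' @param angles projection angles, degrees.
#' @param center rotation center in detector pixels (default geometric).
#' @return a [sinogram()] with `n_angles` rows.
#' @export
radon <- function(image, angles, center = (nrow(image) + 1) / 2) {
  image <- as.matrix(image)
  n <- nrow(image)
  if (ncol(image) != n) abort2("image must be square", "scatomo_grid_error")
  # warn when support leaks outside the inscribed circle
  idx <- which(image != 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    r2 <- (idx[, 1] - (n + 1) / 2)^2 + (idx[, 2] - (n + 1) / 2)^2
    if (max(r2) > ((n - 1) / 2)^2) {
      warning("support extends outside the inscribed circle; projections truncated")
    }
  }
  A <- radon_matrix(n, angles, center)
  v <- as.numeric(A %*% as.vector(image))
  sinogram(t(matrix(v, nrow = n)), angles = angles, x_grid = seq_len(n))
}

# discrete Ram-Lak filter kernel (real space), length 2n-1, spacing 1
.ramlak_kernel <- function(n) {
  k <- -(n - 1):(n - 1)
  h <- numeric(length(k))
  h[k == 0] <- 0.25
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  h
}

#' Filtered back-projection
#'
#' Ramp (Ram-Lak) filtering of each projection followed by back-projection
#' through the transpose of the shared Radon matrix. Fast reference inverse;
#' values may be slightly negative (use [iterative_recon()] for guaranteed
#' non-negative maps).
#'
#' @param sino a [sinogram()].
#' @param center rotation center, detector pixels.
#' @param clip_negative clip negative voxels to zero (default FALSE).
#' @param circle zero voxels outside the inscribed circle (default TRUE);
#'   those voxels leave the detector at some angles and are not reliably
#'   reconstructed.
#' @return a [tomogram()].
#' @export
fbp <- function(sino, center = (ncol(sino$values) + 1) / 2,
                clip_negative = FALSE, circle = TRUE) {
  stopifnot(inherits(sino, "sinogram"))
  P <- sino$values
  n_ang <- nrow(P); n <- ncol(P)
  if (n_ang < 2) abort2("fbp needs at least 2 angles", "scatomo_range_error")
  h <- .ramlak_kernel(n)
  Q <- t(apply(P, 1, function(row) {
    full <- convolve(row, rev(h), type = "open")  # length 3n-2
    full[n:(2 * n - 1)]
  }))
  A <- radon_matrix(n, sino$angles, center)
  dth <- pi * mean(diff(sino$angles)) / 180
  img <- matrix(as.numeric(Matrix::crossprod(A, as.vector(t(Q)))), n, n) * dth
  if (circle) {
    ctr <- (n + 1) / 2
    r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
    img[r2 > ((n - 1) / 2)^2] <- 0
  }
  if (clip_negative) img[img < 0] <- 0
  tomogram(img, feature = sino$feature)
}

#' Non-negative iterative reconstruction (MLEM / SIRT)
#'
#' MLEM applies the multiplicative expectation-maximization update for the
#' Poisson likelihood (non-negative by construction, likelihood non-decreasing
#' each iteration); SIRT applies the simultaneous additive update with
#' projection onto the non-negative orthant. Both use the shared sparse Radon
#' matrix, so forward and back projection are exact adjoints. 100 iterations
#' by default.
#'
#' @param sino a [sinogram()]; negative entries are clipped to zero (counted
#'   in attribute `n_clipped`).
#' @param algorithm `"mlem"` or `"sirt"`.
#' @param n_iter number of iterations (default 100).
#' @param center rotation center, detector pixels.
#' @param track_likelihood if TRUE (MLEM only) attach the Poisson
#'   log-likelihood trace as attribute `loglik`.
#' @return a non-negative [tomogram()].
#' @export
iterative_recon <- function(sino, algorithm = c("mlem", "sirt"), n_iter = 100,
                            center = (ncol(sino$values) + 1) / 2,
                            track_likelihood = FALSE) {
  stopifnot(inherits(sino, "sinogram"), n_iter >= 1)
  algorithm <- match.arg(algorithm)
  y <- as.vector(t(sino$values))
  n_clip <- sum(y < 0)
  y[y < 0] <- 0
  n <- ncol(sino$values)
  if (sum(y) == 0) {
    out <- tomogram(matrix(0, n, n), feature = sino$feature)
    attr(out, "n_clipped") <- n_clip
    return(out)
  }
  A <- radon_matrix(n, sino$angles, center)
  eps <- 1e-12
  if (algorithm == "mlem") {
    sens <- as.numeric(Matrix::crossprod(A, rep(1, length(y))))
    x <- rep(mean(y) / max(mean(sens), eps), n * n)
    ll <- numeric(if (track_likelihood) n_iter else 0)
    for (it in seq_len(n_iter)) {
      ax <- as.numeric(A %*% x)
      ratio <- ifelse(ax > eps, y / ax, 0)
      x <- x * as.numeric(Matrix::crossprod(A, ratio)) / pmax(sens, eps)
      if (track_likelihood) {
        ax2 <- as.numeric(A %*% x)
        pos <- y > 0 & ax2 > 0
        ll[it] <- sum(y[pos] * log(ax2[pos])) - sum(ax2)
      }
    }
  } else {
    rs <- as.numeric(A %*% rep(1, n * n))          # row sums
    cs <- as.numeric(Matrix::crossprod(A, rep(1, length(y))))  # column sums
    x <- rep(0, n * n)
    ll <- numeric(0)
    for (it in seq_len(n_iter)) {
      r <- (y - as.numeric(A %*% x)) / pmax(rs, eps)
      x <- x + as.numeric(Matrix::crossprod(A, r)) / pmax(cs, eps)
      x[x < 0] <- 0
    }
  }
  out <- tomogram(matrix(x, n, n), feature = sino$feature)
  attr(out, "n_clipped") <- n_clip
  if (track_likelihood && algorithm == "mlem") attr(out, "loglik") <- ll
  out
}

#' Rotation-center estimate from a sinogram
#'
#' Registers the projection nearest 0 degrees against the mirrored projection
#' nearest 180 degrees: for the correct center the two are mirror images. The
#' best integer shift of the cross-correlation (after mean subtraction) is
#' refined by a parabolic fit for sub-pixel precision. All reconstructions of
#' one dataset should reuse this single value. Falls back to the average
#' center of mass, with a warning, when no rows near 0/180 degrees exist.
#'
#' @param sino a [sinogram()] whose angles cover approximately `[0, 180]`.
#' @return rotation center in (fractional, 1-based) detector pixels.
#' @export
find_center <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  ang <- sino$angles
  n <- ncol(sino$values)
  i0 <- which.min(abs(ang - 0))
  i180 <- which.min(abs(ang - 180))
  if (abs(ang[i0]) > 5 || abs(ang[i180] - 180) > 5 || i0 == i180) {
    warning("no projections near 0/180 degrees; using center-of-mass fallback")
    w <- pmax(sino$values, 0)
    com <- apply(w, 1, function(r) if (sum(r) > 0) sum(r * seq_len(n)) / sum(r) else NA)
    return(mean(com, na.rm = TRUE))
  }
  # subtracting the low quantile and clipping zeroes the background, so the
  # correlation is weighted by object mass only (no overlap bias) and the
  # estimate is invariant to adding a constant to the sinogram
  strip <- function(v) pmax(v - stats::quantile(v, 0.05, names = FALSE), 0)
  a <- strip(sino$values[i0, ])
  b <- rev(strip(sino$values[i180, ]))
  if (sum(a) == 0 || sum(b) == 0) {
    warning("empty 0/180-degree projections; using geometric center")
    return((n + 1) / 2)
  }
  max_sh <- floor(n / 4)
  shifts <- -max_sh:max_sh
  score <- vapply(shifts, function(s) {
    ia <- max(1, 1 + s):min(n, n + s)
    sum(a[ia] * b[ia - s])
  }, numeric(1))
  k <- which.max(score)
  s_hat <- shifts[k]
  if (k > 1 && k < length(shifts)) {
    y1 <- score[k - 1]; y2 <- score[k]; y3 <- score[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) s_hat <- s_hat + 0.5 * (y1 - y3) / den
  }
  # flipped 180-deg row equals 0-deg row shifted by twice the center offset
  (n + 1) / 2 + s_hat / 2
}

#' Normalize a tomogram against its sinogram
#'
#' Iterative reconstructions are defined up to the data scale; this rescales
#' the map so its voxel total equals the mean over angles of the sinogram row
#' totals (the projection mass, which is angle-independent for valid data).
#'
#' @param tomo a [tomogram()].
#' @param sino the [sinogram()] it was reconstructed from.
#' @return rescaled [tomogram()] with attribute `scale_factor`.
#' @export
normalize_tomogram <- function(tomo, sino) {
  stopifnot(inherits(tomo, "tomogram"), inherits(sino, "sinogram"))
  tot <- sum(tomo$values)
  target <- mean(rowSums(sino$values))
  if (abs(tot) < 1e-300) {
    warning("tomogram total is zero; left unscaled")
    attr(tomo, "scale_factor") <- 1
    return(tomo)
  }
  f <- target / tot
  out <- tomogram(tomo$values * f, voxel_size = tomo$voxel_size,
                  feature = tomo$feature, mask = tomo$mask)
  attr(out, "scale_factor") <- f
  out
}
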