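# Shape-factor pre-scaling, NMF decomposition, rank selection, per-component
# tomograms and per-voxel scattering recomposition.

#' Shape factor for dynamic-range compression
#'
#' Scattering intensity spans several orders of magnitude over q; since the
#' NMF loss is intensity-based, low-intensity features would otherwise be
#' neglected. The factor `s(q) = q^2 / max(q^2)` (clipped below at 1e-4)
#' compresses the dynamic range without introducing new features; recomposed
#' data are divided by the identical factor to restore the original scale.
#'
#' @param q_grid momentum transfer grid, inverse Angstrom, positive.
#' @return object of class `shape_factor` with fields `q_grid` and `s`.
#' @export
shape_factor <- function(q_grid) {
  stopifnot(all(q_grid > 0))
  s <- q_grid^2 / max(q_grid^2)
  s <- pmax(s, 1e-4)
  structure(list(q_grid = as.numeric(q_grid), s = s), class = "shape_factor")
}

#' Apply / undo the shape factor on a profile matrix
#'
#' @param X matrix `[n_obs, n_q]`.
#' @param shape a [shape_factor()].
#' @param undo divide instead of multiply.
#' @return rescaled matrix.
#' @export
apply_shape_factor <- function(X, shape, undo = FALSE) {
  stopifnot(inherits(shape, "shape_factor"), ncol(X) == length(shape$s))
  if (undo) sweep(X, 2, shape$s, `/`) else sweep(X, 2, shape$s, `*`)
}

# non-negative double SVD initialization (Boutsidis & Gallopoulos 2008)
.nndsvd <- function(X, k, seed = 0) {
  sv <- svd(X, nu = k, nv = k)
  n <- nrow(X); m <- ncol(X)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    np_ <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nn_ <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (np_ >= nn_ && np_ > 0) {
      W[, j] <- sqrt(sv$d[j] * np_) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * np_) * vp / sqrt(sum(vp^2))
    } else if (nn_ > 0) {
      W[, j] <- sqrt(sv$d[j] * nn_) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nn_) * vn / sqrt(sum(vn^2))
    }
  }
  # replace exact zeros by small random values so multiplicative updates move
  set.seed(seed)
  eps <- mean(X) * 1e-4
  W[W == 0] <- eps * runif(sum(W == 0))
  H[H == 0] <- eps * runif(sum(H == 0))
  list(W = W, H = H)
}

#' Non-negative matrix factorization (HALS or multiplicative updates)
#'
#' Minimizes the Frobenius loss `||X - W V||_F^2` over non-negative factors.
#' The default solver is hierarchical alternating least squares (HALS, the
#' coordinate-descent family used as the reference default in scikit-learn),
#' which converges to tight residuals; the classic Lee-Seung multiplicative
#' updates are available with `method = "mu"`. Both keep the objective
#' non-increasing per iteration. Initialization is non-negative double SVD
#' (seeded random perturbation of zeros). Negative entries of `X` are clipped
#' to zero (counted in attribute `n_clipped`).
#'
#' @param X matrix `[n_obs, n_q]` of (pre-scaled) profiles.
#' @param method `"hals"` (default) or `"mu"`.
#' @param k number of components, `1 <= k <= min(dim(X))`.
#' @param seed RNG seed for initialization.
#' @param max_iter maximum iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-5).
#' @param init optional warm start, a list with `W` (`[n_obs, k]`) and `H`
#'   (`[k, n_q]`); default is non-negative double SVD.
#' @return list with `weights` (`[n_obs, k]`), `basis` (a `component_basis`:
#'   `vectors` `[k, n_q]`, `k`, `residual` = relative Frobenius error,
#'   `objective` trace).
#' @export
fit_nmf <- function(X, k, seed = 0, max_iter = 500, tol = 1e-5, init = NULL,
                    method = c("hals", "mu")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (k < 1 || k > min(dim(X)))
    abort2("k must be in [1, min(dim(X))]", "scatomo_config_error")
  n_clip <- sum(X < 0)
  X[X < 0] <- 0
  ini <- init %||% .nndsvd(X, k, seed)
  W <- ini$W; H <- ini$H
  stopifnot(nrow(W) == nrow(X), ncol(H) == ncol(X), ncol(W) == k, nrow(H) == k)
  eps <- 1e-12
  nx <- norm(X, "F")
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    if (method == "mu") {
      H <- H * (crossprod(W, X) + eps) / (crossprod(W) %*% H + eps)
      W <- W * (X %*% t(H) + eps) / (W %*% tcrossprod(H) + eps)
    } else {
      # HALS: cyclic exact minimization over each component's row/column
      WtX <- crossprod(W, X); WtW <- crossprod(W)
      for (j in seq_len(k)) {
        num <- WtX[j, ] - WtW[j, -j, drop = FALSE] %*% H[-j, , drop = FALSE]
        H[j, ] <- pmax(as.numeric(num) / max(WtW[j, j], eps), 0)
      }
      XHt <- X %*% t(H); HHt <- tcrossprod(H)
      for (j in seq_len(k)) {
        num <- XHt[, j] - W[, -j, drop = FALSE] %*% HHt[-j, j, drop = FALSE]
        W[, j] <- pmax(as.numeric(num) / max(HHt[j, j], eps), 0)
      }
      # guard against a component collapsing to exact zero
      dead <- colSums(W) == 0 | rowSums(H) == 0
      if (any(dead)) {
        W[, dead] <- eps
        H[dead, ] <- eps
      }
    }
    o <- norm(X - W %*% H, "F")
    obj <- c(obj, o)
    if (is.finite(prev) && abs(prev - o) <= tol * max(o, eps)) break
    prev <- o
  }
  basis <- structure(list(vectors = H, k = k, residual = obj[length(obj)] / nx,
                          objective = obj), class = "component_basis")
  out <- list(weights = W, basis = basis)
  attr(out, "n_clipped") <- n_clip
  out
}

#' @export
print.component_basis <- function(x, ...) {
  cat(sprintf("<component_basis> k = %d, relative residual %.3g\n",
              x$k, x$residual))
  invisible(x)
}

#' NMF rank selection: residual curve and SVD cutoff rule
#'
#' Runs NMF at `k = 1..k_max` and reports the relative-residual curve (more
#' components should not increase the residual). Independently suggests a
#' rank as the number of singular values of `X` at or above `svd_cutoff`
#' times the largest one (the ~1%-of-first-eigenvalue rule).
#'
#' @param X profile matrix.
#' @param k_max largest rank to try (>= 2).
#' @param svd_cutoff fraction of the leading singular value (default 0.01).
#' @param seed,max_iter,tol passed to [fit_nmf()].
#' @return list with `residual_curve` (length `k_max`) and `k_suggested`.
#' @export
select_rank <- function(X, k_max = 8, svd_cutoff = 0.01, seed = 0,
                        max_iter = 500, tol = 1e-5) {
  stopifnot(k_max >= 2)
  # warm-start each rank from the previous solution plus one small extra
  # component (in addition to the default init, keeping the better fit), so
  # the curve is non-increasing instead of jumping between local minima
  res <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    fit <- fit_nmf(X, k, seed = seed, max_iter = max_iter, tol = tol)
    if (!is.null(prev)) {
      eps <- mean(X) * 1e-3
      warm <- list(W = cbind(prev$weights, eps),
                   H = rbind(prev$basis$vectors, eps))
      fit2 <- fit_nmf(X, k, seed = seed, max_iter = max_iter, tol = tol,
                      init = warm)
      if (fit2$basis$residual < fit$basis$residual) fit <- fit2
    }
    res[k] <- fit$basis$residual
    prev <- fit
  }
  d <- svd(as.matrix(X), nu = 0, nv = 0)$d
  list(residual_curve = res, k_suggested = sum(d >= svd_cutoff * d[1]))
}

#' NMF decomposition of a whole scan, with per-component tomograms
#'
#' Flattens the scan's azimuthally integrated profiles into an
#' `[n_frames, n_q]` matrix, applies the shape factor, fits NMF, reshapes the
#' per-frame weights into per-component sinograms and reconstructs one
#' tomogram per component. Frames whose total intensity falls below
#' `min_frame_total` times the maximum frame total are excluded from the fit
#' and recomposed as zeros.
#'
#' @param scan a `scan_set`.
#' @param k number of components.
#' @param shape a [shape_factor()] on the scan's q grid (default built here).
#' @param recon_algorithm `"fbp"`, `"mlem"` or `"sirt"` for the component maps.
#' @param n_iter iterations for the iterative algorithms.
#' @param min_frame_total exclusion threshold (fraction of max frame total).
#' @param seed,max_iter,tol passed to [fit_nmf()].
#' @return object of class `component_maps`: `basis`, `weights`
#'   `[n_frames, k]`, `sinograms` (list), `tomograms` (list), `shape`.
#' @export
decompose_scan <- function(scan, k, shape = shape_factor(scan$q_grid),
                           recon_algorithm = c("fbp", "mlem", "sirt"),
                           n_iter = 100, min_frame_total = 0, seed = 0,
                           max_iter = 500, tol = 1e-5) {
  recon_algorithm <- match.arg(recon_algorithm)
  stopifnot(inherits(scan, "scan_set"))
  prof <- scan_profiles(scan)
  n_ang <- dim(prof)[1]; n_x <- dim(prof)[2]; n_q <- dim(prof)[3]
  X <- matrix(aperm(prof, c(2, 1, 3)), n_ang * n_x, n_q)  # frame = (x within angle)
  Xs <- apply_shape_factor(X, shape)
  tot <- rowSums(X)
  keep <- tot >= min_frame_total * max(tot)
  fit <- fit_nmf(Xs[keep, , drop = FALSE], k, seed = seed,
                 max_iter = max_iter, tol = tol)
  W <- matrix(0, n_ang * n_x, k)
  W[keep, ] <- fit$weights
  ord <- order(scan$angles)
  sinos <- vector("list", k)
  tomos <- vector("list", k)
  for (j in seq_len(k)) {
    vals <- t(matrix(W[, j], n_x, n_ang))[ord, , drop = FALSE]
    sinos[[j]] <- sinogram(vals, angles = scan$angles[ord], x_grid = scan$x_grid,
                           feature = paste0("nmf_", j))
    tomos[[j]] <- switch(recon_algorithm,
      fbp = fbp(sinos[[j]], clip_negative = TRUE),
      iterative_recon(sinos[[j]], algorithm = recon_algorithm, n_iter = n_iter))
    tomos[[j]] <- normalize_tomogram(tomos[[j]], sinos[[j]])
  }
  structure(list(basis = fit$basis, weights = W, sinograms = sinos,
                 tomograms = tomos, shape = shape, k = k,
                 q_grid = scan$q_grid),
            class = "component_maps")
}

#' @export
print.component_maps <- function(x, ...) {
  cat(sprintf("<component_maps> k = %d components, %d frames, residual %.3g\n",
              x$k, nrow(x$weights), x$basis$residual))
  invisible(x)
}

#' Recompose per-voxel scattering profiles
#'
#' The scattering profile at voxel `(y, x)` of the virtual section is the sum
#' over components of the local amplitude times the basis vector, divided by
#' the shape factor to restore the original intensity scale:
#' `I(q; y, x) = sum_c M_c(y, x) V_c(q) / s(q)`.
#'
#' @param maps a `component_maps` (or list of amplitude [tomogram()]s).
#' @param basis the `component_basis` (defaults to `maps$basis`).
#' @param shape the [shape_factor()] (defaults to `maps$shape`).
#' @return array `[n_y, n_x, n_q]` of non-negative voxel profiles.
#' @export
recompose_voxels <- function(maps, basis = maps$basis, shape = maps$shape) {
  tomos <- if (inherits(maps, "component_maps")) maps$tomograms else maps
  if (length(tomos) != basis$k)
    abort2("number of maps must equal basis k", "scatomo_config_error")
  dims <- dim(tomos[[1]]$values)
  n_q <- ncol(basis$vectors)
  M <- vapply(tomos, function(tm) as.vector(tm$values),
              numeric(prod(dims)))                  # [n_voxel, k]
  P <- M %*% basis$vectors                          # [n_voxel, n_q]
  P <- sweep(P, 2, shape$s, `/`)
  P[P < 0] <- 0
  array(P, c(dims, n_q))
}

#' Best assignment of fitted components to reference spectra
#'
#' NMF component order and scale are arbitrary; for validation the fitted
#' basis vectors are matched to reference spectra by maximizing total cosine
#' similarity over all permutations (exhaustive, fine for small k).
#'
#' @param vectors fitted basis matrix `[k, n_q]`.
#' @param reference reference spectra matrix `[k, n_q]`.
#' @return integer permutation `p` such that `vectors[p[j], ]` matches
#'   `reference[j, ]`, with attribute `similarity` (mean matched cosine).
#' @export
match_components <- function(vectors, reference) {
  k <- nrow(reference)
  stopifnot(nrow(vectors) >= k)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- outer(seq_len(nrow(vectors)), seq_len(k),
             Vectorize(function(i, j) cosine(vectors[i, ], reference[j, ])))
  perms <- .permutations(nrow(vectors))
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- sum(S[cbind(p[seq_len(k)], seq_len(k))])
    if (v > best_val) { best_val <- v; best <- p[seq_len(k)] }
  }
  structure(best, similarity = best_val / k)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1)) {
      q <- p
      q[q >= i] <- q[q >= i] + 1L
      out[[length(out) + 1]] <- c(i, q)
    }
  }
  out
}
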