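# Composition segmentation of the virtual section: unit-normalized component
# vectors, k-means with k-means++ seeding, inertia elbow, centroid profiles.

#' Unit-normalized composition features from component maps
#'
#' Each in-support voxel is a point in component space with coordinates given
#' by the NMF component amplitudes. Because only the relative composition is
#' of interest, every voxel vector is scaled to unit Euclidean length. Voxels
#' whose total amplitude falls below `min_total` times the maximum voxel
#' total are marked missing and excluded.
#'
#' @param maps a `component_maps` (or list of amplitude [tomogram()]s).
#' @param min_total exclusion threshold as a fraction of the maximum voxel
#'   total (default 0.05, shared with the CI mask default).
#' @return list with `features` (`[n_valid, k]`, unit rows), `valid` (logical
#'   vector over voxels, column-major), and `dims` of the section.
#' @export
normalize_composition <- function(maps, min_total = 0.05) {
  tomos <- if (inherits(maps, "component_maps")) maps$tomograms else maps
  k <- length(tomos)
  if (k < 2) abort2("need at least 2 components", "scatomo_config_error")
  dims <- dim(tomos[[1]]$values)
  M <- vapply(tomos, function(tm) as.vector(tm$values), numeric(prod(dims)))
  M[M < 0] <- 0
  tot <- rowSums(M)
  valid <- tot >= min_total * max(tot) & tot > 0
  nrm <- sqrt(rowSums(M^2))
  F <- M[valid, , drop = FALSE] / nrm[valid]
  list(features = F, valid = valid, dims = dims)
}

# k-means++ seeding (Arthur & Vassilvitskii 2007)
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1, prob = p)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' k-means segmentation of composition features
#'
#' Lloyd iterations started from k-means++ seeds, best of `n_init` restarts
#' by inertia (the summed squared distance to the assigned centroid, the
#' k-means objective).
#'
#' @param comp result of [normalize_composition()] (or a plain feature
#'   matrix).
#' @param n_clusters number of clusters `N_c` (default 3, which keeps the
#'   maps readable; use [inertia_curve()] to inspect the elbow).
#' @param seed RNG seed.
#' @param n_init number of restarts (default 10).
#' @return object of class `cluster_result`: `labels` (per-voxel id or `NA`,
#'   as a matrix when voxel dims are known), `centroids` `[N_c, k]`,
#'   `inertia`, `sizes`.
#' @export
kmeans_segment <- function(comp, n_clusters = 3, seed = 0, n_init = 10) {
  X <- if (is.list(comp)) comp$features else as.matrix(comp)
  if (n_clusters < 2) abort2("n_clusters must be >= 2", "scatomo_config_error")
  if (nrow(X) < n_clusters)
    abort2("fewer valid voxels than clusters", "scatomo_data_error")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    ctrs <- .kmeanspp_centers(X, n_clusters)
    km <- suppressWarnings(
      kmeans(X, centers = ctrs, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  if (is.list(comp) && !is.null(comp$valid)) {
    lab_full <- rep(NA_integer_, length(comp$valid))
    lab_full[comp$valid] <- labels
    labels <- matrix(lab_full, comp$dims[1], comp$dims[2])
  }
  structure(list(labels = labels, centroids = best$centers,
                 inertia = best$tot.withinss, sizes = best$size,
                 n_clusters = n_clusters),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, inertia %.4g, sizes: %s\n",
              x$n_clusters, x$inertia, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Inertia as a function of the number of clusters
#'
#' The elbow of this curve guides the choice of `N_c`; there is rarely a
#' single best value, so the choice is left to the user.
#'
#' @param comp result of [normalize_composition()] or a feature matrix.
#' @param k_range candidate cluster counts.
#' @param seed,n_init passed to [kmeans_segment()].
#' @return named numeric vector of inertias.
#' @export
inertia_curve <- function(comp, k_range = 2:8, seed = 0, n_init = 10) {
  vals <- vapply(k_range, function(k)
    kmeans_segment(comp, n_clusters = k, seed = seed, n_init = n_init)$inertia,
    numeric(1))
  names(vals) <- k_range
  vals
}

#' Representative scattering profile of each cluster
#'
#' The centroid coordinates in (normalized) component space are recomposed
#' through the NMF basis and the shape factor:
#' `I_c(q) = [centroid_c . V](q) / s(q)`. Unlike raw NMF vectors, these are
#' actual scattering intensities and therefore interpretable.
#'
#' @param result a [kmeans_segment()] result.
#' @param basis the `component_basis`.
#' @param shape the [shape_factor()] used before decomposition.
#' @return list of [profile1d()], one per cluster.
#' @export
cluster_profiles <- function(result, basis, shape) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(basis, "component_basis"))
  if (ncol(result$centroids) != basis$k)
    abort2("centroid dimension must match basis k", "scatomo_config_error")
  P <- result$centroids %*% basis$vectors
  P <- sweep(P, 2, shape$s, `/`)
  P[P < 0] <- 0
  lapply(seq_len(nrow(P)), function(i) profile1d(shape$q_grid, P[i, ]))
}
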