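# Shared fixtures, memoized so expensive scans are simulated once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

q_grid_fine <- function() seq(0.04, 2.0, by = 0.01)
q_grid_coarse <- function() seq(0.04, 2.0, by = 0.02)

# small ring-phantom scan with full frames (reduce / featuremaps / mfa basics)
small_scan <- function() fixture("small_scan", function() {
  comps <- build_component_library(q_grid_coarse())
  ph <- make_ring_phantom(n_voxels = 32, voxel_size = 5, outer_radius = 70,
                          wall_thickness = 35)
  scan <- simulate_scan(ph, comps,
                        acquisition_config(angles = seq(0, 180, by = 6)),
                        phi_grid = seq(-90, 90, by = 6))
  list(scan = scan, phantom = ph, components = comps)
})

# mid-size ring scan for MFA gradient recovery (shared with acceptance tests)
mfa_scan <- function() fixture("mfa_scan", function() {
  comps <- build_component_library(q_grid_coarse())
  ph <- make_ring_phantom(n_voxels = 48, voxel_size = 5, outer_radius = 105,
                          wall_thickness = 55, mfa_outer = 5, mfa_inner = 30)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 3)),
    phi_grid = seq(-90, 90, by = 3)))
  list(scan = scan, phantom = ph, components = comps)
})

# separable 3-component blob scan for NMF recovery (shared with acceptance)
blob_scan <- function() fixture("blob_scan", function() {
  comps <- build_component_library(q_grid_fine())
  comps3 <- comps[c("cellulose", "amorphous", "starch")]
  ph <- make_blob_phantom(n_voxels = 48)
  scan <- correct_scan(simulate_scan(
    ph, comps3, acquisition_config(angles = seq(0, 180, by = 3)),
    phi_grid = seq(-90, 90, by = 3), store = "profiles"))
  list(scan = scan, phantom = ph, components = comps3)
})

# uniform disk image + sinogram at the standard angular sampling
disk_fixture <- function(n = 64, radius = 20) {
  ctr <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  list(image = matrix(as.numeric(r <= radius), n, n), r = r, ctr = ctr)
}

# area-coverage anti-aliased disk (supersampled pixel coverage fractions)
aa_disk <- function(n, radius, ss = 8) {
  ctr <- (n + 1) / 2
  off <- seq(-0.5 + 1 / (2 * ss), 0.5 - 1 / (2 * ss), length.out = ss)
  m <- matrix(0, n, n)
  for (dx in off) for (dy in off) {
    r2 <- outer((seq_len(n) + dy - ctr)^2, (seq_len(n) + dx - ctr)^2, `+`)
    m <- m + (r2 <= radius^2)
  }
  m / ss^2
}

# independent brute-force projector: supersampled mass binning (no shared
# code with the package's sparse-matrix path)
brute_radon_row <- function(image, theta_deg, oversamp = 8) {
  n <- nrow(image)
  ctr <- (n + 1) / 2
  th <- theta_deg * pi / 180
  step <- 1 / oversamp
  g <- seq(1 - 0.5 + step / 2, n + 0.5 - step / 2, by = step)
  xs <- rep(g - ctr, times = length(g))
  ys <- rep(g - ctr, each = length(g))
  # pixel value at each subsample (nearest pixel)
  px <- round(xs + ctr); py <- round(ys + ctr)
  val <- image[cbind(py, px)] / oversamp^2
  # detector coordinate of each subsample after rotating the sample by theta
  s <- xs * cos(th) + ys * sin(th)
  bin <- round(s + ctr)
  keep <- bin >= 1 & bin <= n & val != 0
  out <- numeric(n)
  tab <- tapply(val[keep], bin[keep], sum)
  out[as.integer(names(tab))] <- tab
  out
}

# brute-force global NNLS by active-set enumeration (small n only)
qp_nnls_oracle <- function(A, y) {
  n <- ncol(A)
  best <- rep(0, n)
  best_val <- sum(y^2)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) == 0) next
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(solve(crossprod(As), crossprod(As, y)),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-10)) next
    x <- rep(0, n); x[S] <- xs
    val <- sum((y - A %*% x)^2)
    if (val < best_val - 1e-12) { best_val <- val; best <- x }
  }
  best
}
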