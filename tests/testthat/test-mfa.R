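# Microfibril-angle analysis: azimuthal profiles, discrete-MFA basis,
# regularized NNLS, nominal MFA, per-voxel recovery.

test_that("MFA basis columns are paired Gaussians of unit integral", {
  phig <- seq(-90, 90, by = 1)
  basis <- build_mfa_basis(phig)
  expect_identical(dim(basis$A), c(181L, 31L))
  expect_identical(basis$mfa_values, seq(0, 90, by = 3))
  dphi <- 1
  expect_equal(colSums(basis$A) * dphi, rep(1, 31), tolerance = 1e-6)
  # mu = 0: single symmetric peak at phi = 0
  c0 <- basis$A[, 1]
  expect_identical(which.max(c0), 91L)
  expect_equal(c0, rev(c0))
  # mu = 45: maxima at +/-45, equator below half max for sigma = 5
  c45 <- basis$A[, basis$mfa_values == 45]
  expect_setequal(phig[c45 > 0.999 * max(c45)], c(-45, 45))
  expect_lt(c45[91], 0.5 * max(c45))
})

test_that("regularized NNLS matches a quadratic-programming oracle", {
  set.seed(31)
  for (rep in 1:8) {
    A <- matrix(runif(12 * 6), 12, 6)
    y <- as.numeric(A %*% pmax(rnorm(6), 0)) + abs(rnorm(12, sd = 0.1))
    for (lam in list(c(0, 0), c(0.05, 0.2))) {
      n <- ncol(A)
      D <- diag(n); D[cbind(2:n, 1:(n - 1))] <- -1
      Aaug <- rbind(A, sqrt(lam[1]) * diag(n), sqrt(lam[2]) * D)
      yaug <- c(y, rep(0, 2 * n))
      oracle <- qp_nnls_oracle(Aaug, yaug)
      got <- nnls_regularized(A, y, lam[1], lam[2])$weights
      expect_lt(max(abs(got - oracle)), 1e-6)
    }
  }
})

test_that("NNLS edge cases: exact basis column, zero data, residual monotone in lambda", {
  phig <- seq(-90, 90, by = 3)
  basis <- build_mfa_basis(phig)
  j <- which(basis$mfa_values == 30)
  fit <- nnls_regularized(basis, basis$A[, j], 0, 0)
  expect_lt(max(abs(fit$weights - (seq_len(31) == j))), 1e-8)
  expect_true(all(nnls_regularized(basis, rep(0, 61), 0.1, 0.1)$weights == 0))
  # residual grows (weakly) with regularization strength
  set.seed(4)
  y <- as.numeric(basis$A %*% runif(31))
  r0 <- nnls_regularized(basis, y, 0, 0)$residual
  r1 <- nnls_regularized(basis, y, 0.01, 0.1)$residual
  r2 <- nnls_regularized(basis, y, 1, 10)$residual
  expect_lte(r0, r1 + 1e-12)
  expect_lte(r1, r2 + 1e-12)
  expect_error(nnls_regularized(basis, rep(0, 10)), class = "scatomo_grid_error")
})

test_that("nominal MFA is the intensity-weighted mean absolute azimuth", {
  phig <- seq(-90, 90, by = 1)
  spike0 <- numeric(181); spike0[91] <- 5
  expect_equal(nominal_mfa(azim_profile(phig, spike0)), 0)
  spikes <- numeric(181); spikes[phig == -30] <- 2; spikes[phig == 30] <- 2
  expect_equal(nominal_mfa(azim_profile(phig, spikes)), 30)
  expect_equal(nominal_mfa(azim_profile(phig, rep(1, 181))), 45,
               tolerance = 0.01)
  # scale invariance and the zero-intensity case
  set.seed(6)
  y <- runif(181)
  expect_equal(nominal_mfa(azim_profile(phig, 7 * y)),
               nominal_mfa(azim_profile(phig, y)))
  expect_true(is.na(nominal_mfa(azim_profile(phig, rep(0, 181)))))
})

test_that("projection-averaged profile isolates the crystalline azimuthal signal", {
  # isotropic-only phantom: profile ~ 0 after baseline subtraction
  comps <- build_component_library(q_grid_coarse())["amorphous"]
  ph <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                          wall_thickness = 26)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 15)),
    phi_grid = seq(-90, 90, by = 5)))
  pav <- projection_averaged_profile(scan, c(1.55, 1.65))
  pre <- projection_averaged_profile(scan, c(1.55, 1.65), baseline_window = NULL)
  # the sloping halo leaves a phi-flat pedestal; what matters for the MFA
  # analysis is that no azimuthal structure survives and the level drops
  expect_lt(max(pav$intensity) - min(pav$intensity), 0.02 * max(pre$intensity))
  expect_lt(mean(pav$intensity), 0.65 * mean(pre$intensity))
  # MFA = 0 phantom: single cellulose peak at the equator
  comps_c <- build_component_library(q_grid_coarse())["cellulose"]
  ph0 <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                           wall_thickness = 26, mfa_outer = 0, mfa_inner = 0)
  scan0 <- correct_scan(simulate_scan(
    ph0, comps_c, acquisition_config(angles = seq(0, 180, by = 15)),
    phi_grid = seq(-90, 90, by = 5)))
  p0 <- projection_averaged_profile(scan0, c(1.55, 1.65))
  expect_identical(p0$phi_grid[which.max(p0$intensity)], 0)
  # MFA = 20 phantom: symmetric maxima near +/-20 degrees
  ph20 <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                            wall_thickness = 26, mfa_outer = 20, mfa_inner = 20)
  scan20 <- correct_scan(simulate_scan(
    ph20, comps_c, acquisition_config(angles = seq(0, 180, by = 15)),
    phi_grid = seq(-90, 90, by = 5)))
  p20 <- projection_averaged_profile(scan20, c(1.55, 1.65))
  pos <- p20$phi_grid[p20$phi_grid > 0][which.max(p20$intensity[p20$phi_grid > 0])]
  neg <- p20$phi_grid[p20$phi_grid < 0][which.max(p20$intensity[p20$phi_grid < 0])]
  expect_lte(abs(pos - 20), 5)
  expect_lte(abs(neg + 20), 5)
})

test_that("whole-sample MFA distribution is recovered within one basis step", {
  # constant-MFA phantom: planted delta distribution at 18 degrees
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 32, voxel_size = 5, outer_radius = 70,
                          wall_thickness = 35, mfa_outer = 18, mfa_inner = 18)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 7.5)),
    phi_grid = seq(-90, 90, by = 3)))
  pav <- projection_averaged_profile(scan, c(1.55, 1.65))
  basis <- build_mfa_basis(scan$phi_grid)
  # noiseless data: gentle regularization (lambda is adjusted per dataset)
  fit <- nnls_regularized(basis, pav$intensity, 1e-3, 1e-3)
  planted <- as.numeric(basis$mfa_values == 18)
  expect_lte(emd_1d(fit$weights, planted, basis$mfa_values), 3)
})

test_that("per-phi tomograms of an isotropic phantom are flat in phi", {
  comps <- build_component_library(q_grid_coarse())["amorphous"]
  ph <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                          wall_thickness = 26)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 10)),
    phi_grid = seq(-90, 90, by = 15)))
  stack <- per_phi_tomograms(scan, c(1.28, 1.37), baseline_window = NULL)
  v <- stack$values
  core <- ph$support
  spread <- apply(v, 3, function(m) m[core])
  rel <- (apply(spread, 1, max) - apply(spread, 1, min)) /
    pmax(apply(spread, 1, mean), 1e-12)
  expect_lt(median(rel), 0.05)
  # zero scan gives a zero stack
  ph0 <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                           wall_thickness = 26, wall_density = 0,
                           starch_gradient = 0)
  scan0 <- simulate_scan(ph0, comps,
                         acquisition_config(angles = seq(0, 180, by = 10)),
                         phi_grid = seq(-90, 90, by = 15))
  expect_true(all(per_phi_tomograms(scan0, c(1.28, 1.37),
                                    baseline_window = NULL)$values == 0))
})

test_that("summing the per-phi stack reproduces the peak-window tomogram", {
  fx <- mfa_scan()
  stack <- per_phi_tomograms(fx$scan, c(1.55, 1.65), baseline_window = NULL)
  dphi <- mean(diff(fx$scan$phi_grid))
  summed <- apply(stack$values, c(1, 2), mean) * 180
  sino <- build_sinogram(fx$scan, c(1.55, 1.65))
  direct <- fbp(sino, clip_negative = TRUE)$values
  core <- fx$phantom$support
  expect_lt(sqrt(mean((summed[core] - direct[core])^2)) / mean(direct[core]),
            0.02)
})

test_that("per-voxel nominal MFA reproduces the planted radial gradient", {
  fx <- mfa_scan()
  stack <- per_phi_tomograms(fx$scan, c(1.55, 1.65))
  basis <- build_mfa_basis(stack$phi_grid)
  mm <- mfa_maps(stack, basis, distributions = FALSE)
  ok <- !is.na(mm$phi_a$values) & fx$phantom$support
  expect_gt(sum(ok), 500)
  expect_gte(cor(mm$phi_a$values[ok], fx$phantom$mfa_map[ok],
                 method = "spearman"), 0.9)
  # masked voxels carry no value
  expect_true(all(is.na(mm$phi_a$values[!mm$valid])))
})

test_that("per-voxel MFA distributions peak at the planted constant angle", {
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 32, voxel_size = 5, outer_radius = 70,
                          wall_thickness = 35, mfa_outer = 15, mfa_inner = 15)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 6)),
    phi_grid = seq(-90, 90, by = 3)))
  stack <- per_phi_tomograms(scan, c(1.55, 1.65))
  basis <- build_mfa_basis(stack$phi_grid)
  mm <- mfa_maps(stack, basis, distributions = TRUE)
  modes <- basis$mfa_values[apply(mm$distributions, 1, which.max)]
  expect_gte(mean(abs(modes - 15) <= 3), 0.9)
})
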