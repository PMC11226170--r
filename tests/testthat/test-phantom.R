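# Phantom generation and the forward scan simulator.

test_that("component library reproduces the reference peak structure", {
  qg <- seq(0.04, 2.0, by = 0.01)
  lib <- build_component_library(qg)
  expect_true(all(c("cellulose", "amorphous", "starch", "saxs") %in% names(lib)))
  # A-type starch local maxima at 1.07, 1.21, 1.27 1/A
  st <- lib$starch$intensity
  for (q0 in c(1.07, 1.21, 1.27)) {
    i <- which.min(abs(qg - q0))
    expect_true(st[i] > st[i - 2] && st[i] > st[i + 2])
  }
  # cellulose: amorphous-valley window integral below the (020) peak window
  cell <- profile1d(qg, lib$cellulose$intensity)
  expect_lt(window_intensity(cell, 1.28, 1.37), window_intensity(cell, 1.55, 1.63))
  # (020) peak falls inside 1.55-1.63
  expect_true(qg[which.max(lib$cellulose$intensity)] >= 1.55)
  expect_true(qg[which.max(lib$cellulose$intensity)] <= 1.63)
  # non-negativity everywhere
  for (cm in lib) expect_gte(min(cm$intensity), 0)
  # azimuthal classes: crystalline cellulose and the fibril peak are equatorial
  expect_identical(lib$cellulose$azimuthal_class, "equatorial")
  expect_identical(lib$saxs$azimuthal_class, "equatorial")
  expect_identical(lib$amorphous$azimuthal_class, "isotropic")
  expect_error(build_component_library(seq(0.5, 2, by = 0.01)),
               class = "scatomo_config_error")
})

test_that("ring phantom geometry, gradients and mass are as prescribed", {
  ph <- make_ring_phantom(n_voxels = 64, voxel_size = 5, outer_radius = 140,
                          wall_thickness = 70, starch_gradient = 0,
                          starch_uniform = 0.3, mfa_outer = 10, mfa_inner = 10)
  # starch_gradient = 0 -> uniform over the annulus
  expect_equal(diff(range(ph$concentration$starch[ph$support])), 0)
  # constant MFA on the support
  expect_true(all(ph$mfa_map[ph$support] == 10))
  # voxel-sum of total wall mass matches the analytic annulus area
  wall <- ph$concentration$cellulose + ph$concentration$amorphous
  area_voxels <- pi * (140^2 - 70^2) / 5^2
  expect_equal(sum(wall), area_voxels, tolerance = 0.01)
  # geometry errors
  expect_error(make_ring_phantom(n_voxels = 32, voxel_size = 5,
                                 outer_radius = 140, wall_thickness = 70),
               class = "scatomo_config_error")
  expect_error(make_ring_phantom(outer_radius = 100, wall_thickness = 120),
               class = "scatomo_config_error")
})

test_that("blob phantom places disjoint single-component domains inside the circle", {
  ph <- make_blob_phantom(n_voxels = 48)
  n <- 48; ctr <- (n + 1) / 2
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, `+`))
  expect_true(all(r[ph$support] <= (n - 1) / 2))
  overlap <- Reduce(`+`, lapply(ph$concentration, function(m) (m > 0) * 1))
  expect_lte(max(overlap), 1)
  expect_true(all(vapply(ph$concentration, sum, numeric(1)) > 0))
})

test_that("simulated frames are rotation-invariant after azimuthal integration", {
  fx <- small_scan()
  corr <- correct_scan(fx$scan)
  prof <- scan_profiles(corr)
  rowtot <- apply(prof, 1, sum)
  expect_lt((max(rowtot) - min(rowtot)) / mean(rowtot), 0.005)
  # cellulose-window x-sum at 0 vs 90 degrees within 0.5% of each other
  sino <- build_sinogram(corr, c(1.55, 1.63))
  i0 <- which.min(abs(sino$angles - 0)); i90 <- which.min(abs(sino$angles - 90))
  expect_equal(sum(sino$values[i0, ]), sum(sino$values[i90, ]),
               tolerance = 0.005)
})

test_that("empty phantom gives zero frames and unit transmission", {
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 16, voxel_size = 5, outer_radius = 35,
                          wall_thickness = 18, wall_density = 0,
                          starch_gradient = 0)
  scan <- simulate_scan(ph, comps, acquisition_config(angles = c(0, 90)),
                        phi_grid = seq(-90, 90, by = 30))
  expect_true(all(scan$frames == 0))
  expect_true(all(scan$it == 1))
  sino <- build_sinogram(scan, c(1.55, 1.63))
  expect_true(all(sino$values == 0))
})

test_that("identical seed reproduces a noisy scan bit for bit", {
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 16, voxel_size = 5, outer_radius = 35,
                          wall_thickness = 18)
  acq <- acquisition_config(angles = seq(0, 180, by = 30), photon_scale = 50,
                            seed = 7)
  s1 <- simulate_scan(ph, comps, acq, phi_grid = seq(-90, 90, by = 15))
  s2 <- simulate_scan(ph, comps, acq, phi_grid = seq(-90, 90, by = 15))
  expect_identical(s1$frames, s2$frames)
  acq3 <- acquisition_config(angles = seq(0, 180, by = 30), photon_scale = 50,
                             seed = 8)
  s3 <- simulate_scan(ph, comps, acq3, phi_grid = seq(-90, 90, by = 15))
  expect_false(identical(s1$frames, s3$frames))
  # Poisson noise is unbiased: totals agree within a few percent
  expect_equal(sum(s1$frames), sum(simulate_scan(ph, comps,
    acquisition_config(angles = seq(0, 180, by = 30)),
    phi_grid = seq(-90, 90, by = 15))$frames), tolerance = 0.05)
})

test_that("interleaved ordering is a permutation and damage decays over time", {
  ord <- interleave_order(121, 8)
  expect_setequal(ord, 1:121)
  expect_identical(ord[1:4], c(1L, 9L, 17L, 25L))
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 16, voxel_size = 5, outer_radius = 35,
                          wall_thickness = 18)
  acq <- acquisition_config(angles = seq(0, 180, by = 15),
                            ordering = "interleaved", n_groups = 4,
                            damage_rate = 2e-4)
  scan <- simulate_scan(ph, comps, acq, phi_grid = seq(-90, 90, by = 30),
                        store = "profiles")
  sino <- build_sinogram(scan, c(1.55, 1.63))
  nodmg <- simulate_scan(ph, comps,
    acquisition_config(angles = seq(0, 180, by = 15)),
    phi_grid = seq(-90, 90, by = 30), store = "profiles")
  sino0 <- build_sinogram(nodmg, c(1.55, 1.63))
  # the damage monitor flags the decayed interleaved scan
  expect_gt(damage_score(sino), 5 * max(damage_score(sino0), 1e-6))
  # frames acquired late have lost intensity
  first <- scan$acq_order[1]; last <- scan$acq_order[length(scan$acq_order)]
  expect_lt(sum(scan$profiles[last, , ]) / sum(nodmg$profiles[last, , ]),
            sum(scan$profiles[first, , ]) / sum(nodmg$profiles[first, , ]))
})

test_that("mass of any feature sinogram is angle-independent (linearity in the phantom)", {
  fx <- small_scan()
  corr <- correct_scan(fx$scan)
  for (w in list(c(0.1, 0.15), c(1.28, 1.37))) {
    sino <- build_sinogram(corr, w)
    rt <- rowSums(sino$values)
    expect_lt((max(rt) - min(rt)) / mean(rt), 0.005)
  }
})
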