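# Frame reduction: conversions, azimuthal integration, corrections, despiking.

test_that("q <-> scattering-angle conversion matches the starch peak angles at 8 keV", {
  # A-type starch reflections: 2theta = 15.2, 17.2, 18.0 deg at 8 keV map to
  # q ~ 1.07, 1.21, 1.27 1/A
  expect_equal(q_from_angle(15.2, 8), 1.07, tolerance = 0.005)
  expect_equal(q_from_angle(17.2, 8), 1.21, tolerance = 0.005)
  expect_equal(q_from_angle(18.0, 8), 1.27, tolerance = 0.005)
  expect_equal(angle_from_q(1.07, 8), 15.2, tolerance = 0.05)
  expect_identical(q_from_angle(0, 12), 0)
  expect_identical(angle_from_q(0, 12), 0)
})

test_that("conversion round-trips and rejects unphysical input", {
  set.seed(1)
  q <- runif(100, 0, 3)
  expect_equal(q_from_angle(angle_from_q(q, 11.3), 11.3), q, tolerance = 1e-10)
  expect_error(q_from_angle(200, 8), class = "scatomo_range_error")
  expect_error(angle_from_q(50, 8), class = "scatomo_range_error")
  expect_error(q_from_angle(10, -1), class = "scatomo_range_error")
})

test_that("azimuthal average is a mask-aware mean times the 180-degree range", {
  qg <- seq(0.1, 1, by = 0.1)
  phig <- seq(-90, 90, by = 5)
  m <- qphi_map(matrix(2.5, 10, 37), qg, phig)
  expect_equal(azimuthal_average(m)$intensity, rep(450, 10))
  # masking half the bins of a uniform map leaves the result unchanged
  mask <- matrix(TRUE, 10, 37); mask[, 1:18] <- FALSE
  mm <- qphi_map(matrix(2.5, 10, 37), qg, phig, mask = mask)
  expect_equal(azimuthal_average(mm)$intensity, rep(450, 10))
  # fully masked row is flagged missing, not zero
  mask2 <- matrix(TRUE, 10, 37); mask2[3, ] <- FALSE
  m2 <- qphi_map(matrix(1, 10, 37), qg, phig, mask = mask2)
  expect_true(is.na(azimuthal_average(m2)$intensity[3]))
})

test_that("azimuthal average of a split-peak map agrees with direct quadrature", {
  qg <- seq(0.1, 1, by = 0.1)
  phig <- seq(-90, 90, by = 3)
  intens <- matrix(0, 10, length(phig))
  for (p0 in c(-30, 30)) intens <- intens +
    outer(seq(1, 2, length.out = 10), exp(-0.5 * ((phig - p0) / 6)^2))
  m <- qphi_map(intens, qg, phig)
  got <- azimuthal_average(m)$intensity
  oracle <- apply(intens, 1, function(row) pracma::trapz(phig, row))
  expect_equal(got, oracle, tolerance = 0.02)
  # linearity and phi-permutation invariance of the plain mean
  m3 <- qphi_map(3 * intens, qg, phig)
  expect_equal(azimuthal_average(m3)$intensity, 3 * got, tolerance = 1e-12)
  perm <- sample(length(phig))
  mper <- qphi_map(intens[, perm], qg, sort(phig), i0 = 1, it = 1)
  expect_equal(azimuthal_average(mper)$intensity, got, tolerance = 1e-12)
})

test_that("equatorial profile picks the band around phi = 0", {
  qg <- seq(0.1, 1, by = 0.1)
  phig <- seq(-90, 90, by = 5)
  m <- qphi_map(matrix(4, 10, 37), qg, phig)
  expect_equal(equatorial_profile(m, 10)$intensity, rep(4, 10))
  # split peaks at +/-20 deg: the equator is a valley
  intens <- outer(rep(1, 10),
                  exp(-0.5 * ((phig - 20) / 5)^2) + exp(-0.5 * ((phig + 20) / 5)^2))
  ms <- qphi_map(intens, qg, phig)
  eq <- equatorial_profile(ms, 5)$intensity
  full <- azimuthal_average(ms)$intensity / 180
  expect_true(all(eq < full))
  # half_width 0 equals the direct phi = 0 slice
  expect_equal(equatorial_profile(ms, 0)$intensity,
               intens[, phig == 0])
})

test_that("frame correction removes background and undoes absorption", {
  qg <- seq(0.1, 1, by = 0.1)
  phig <- seq(-90, 90, by = 10)
  bg <- profile1d(qg, rep(2, 10))
  # empty sample: I = background, T = 1 -> zeros
  m <- qphi_map(matrix(2, 10, 19), qg, phig, i0 = 1, it = 1)
  expect_true(all(correct_frame(m, bg)$intensity == 0))
  # T = 0.5, zero background -> intensity doubled
  m2 <- qphi_map(matrix(3, 10, 19), qg, phig, i0 = 1, it = 0.5)
  out <- correct_frame(m2, profile1d(qg, rep(0, 10)))
  expect_equal(out$intensity, matrix(6, 10, 19))
  # negative results are clipped and counted
  m3 <- qphi_map(matrix(1, 10, 19), qg, phig, i0 = 1, it = 1)
  out3 <- correct_frame(m3, profile1d(qg, rep(5, 10)))
  expect_true(all(out3$intensity == 0))
  expect_identical(attr(out3, "n_clipped"), 190L)
})

test_that("1-D correction commutes with azimuthal averaging for isotropic background", {
  qg <- seq(0.1, 1, by = 0.1)
  phig <- seq(-90, 90, by = 10)
  set.seed(3)
  intens <- matrix(runif(190, 1, 4), 10, 19)
  bg <- profile1d(qg, runif(10, 0, 0.5))
  m <- qphi_map(intens, qg, phig, i0 = 1, it = 0.7)
  path1 <- azimuthal_average(correct_frame(m, bg))$intensity
  raw <- azimuthal_average(m)$intensity
  path2 <- (raw - 0.7 * 180 * bg$intensity) / 0.7
  expect_equal(path1, path2, tolerance = 1e-10)
})

test_that("corrected sinogram tracks pure concentration line integrals", {
  # single-component phantom so the feature window sees that component alone
  comps <- build_component_library(q_grid_coarse())["cellulose"]
  ph <- make_ring_phantom(n_voxels = 24, voxel_size = 5, outer_radius = 52,
                          wall_thickness = 26)
  scan <- correct_scan(simulate_scan(
    ph, comps, acquisition_config(angles = seq(0, 180, by = 10)),
    phi_grid = seq(-90, 90, by = 10), store = "profiles"))
  sino <- build_sinogram(scan, c(1.55, 1.63), feature = "cellulose")
  A <- radon_matrix(24, sort(scan$angles))
  truth <- t(matrix(as.numeric(
    A %*% as.vector(ph$concentration$cellulose)), 24))
  fitv <- as.vector(sino$values); tv <- as.vector(truth)
  # proportional within 1 percent (normalized shapes)
  expect_lt(max(abs(fitv / sum(fitv) - tv / sum(tv))) / max(tv / sum(tv)), 0.01)
})

test_that("rolling-ball baseline passes under broad features and kills spikes", {
  qg <- seq(0, 2, by = 0.01)
  smooth <- profile1d(qg, 1 + qg^1.5)
  rb <- rolling_ball(smooth, radius = 5)
  expect_equal(rb$baseline$intensity, smooth$intensity, tolerance = 1e-3)
  expect_equal(rb$despiked$intensity, smooth$intensity, tolerance = 1e-3)
  # single-bin spike of height 50 on flat background 2
  y <- rep(2, 201); y[100] <- 52
  sp <- rolling_ball(profile1d(qg, y), radius = 5)
  expect_equal(sp$despiked$intensity[100], 2, tolerance = 1e-9)
  expect_true(all(sp$baseline$intensity <= y + 1e-12))
  # idempotence
  again <- rolling_ball(sp$despiked, radius = 5)
  expect_equal(again$despiked$intensity, sp$despiked$intensity,
               tolerance = 1e-12)
  expect_error(rolling_ball(smooth, radius = 300), class = "scatomo_range_error")
})

test_that("rolling-ball baseline subtraction recovers narrow starch peak areas", {
  qg <- seq(0.8, 1.6, by = 0.01)
  halo <- 3 * exp(-0.5 * ((qg - 1.35) / 0.30)^2)
  areas <- c(0.8, 0.6, 1.0) * 0.015 * sqrt(2 * pi)
  peaks <- 0.8 * exp(-0.5 * ((qg - 1.07) / 0.015)^2) +
    0.6 * exp(-0.5 * ((qg - 1.21) / 0.015)^2) +
    1.0 * exp(-0.5 * ((qg - 1.27) / 0.015)^2)
  rb <- rolling_ball(profile1d(qg, halo + peaks), radius = 8)
  resid <- (halo + peaks) - rb$baseline$intensity
  for (i in seq_along(areas)) {
    w <- c(1.07, 1.21, 1.27)[i] + c(-0.04, 0.04)
    sel <- qg >= w[1] & qg <= w[2]
    expect_equal(pracma::trapz(qg[sel], resid[sel]), areas[i],
                 tolerance = 0.1)
  }
})

test_that("q-smearing estimate is linear and matches the beamline geometry", {
  sm <- q_smearing(5, 350, 1.6)
  expect_equal(sm$relative, 5 / 350)
  expect_equal(sm$relative, 0.015, tolerance = 0.05)
  expect_equal(sm$absolute, 0.02, tolerance = 0.15)
  expect_identical(q_smearing(0, 350, 1.6), list(relative = 0, absolute = 0))
  sm2 <- q_smearing(10, 350, 1.6)
  expect_equal(sm2$relative, 2 * sm$relative)
  expect_equal(sm2$absolute, 2 * sm$absolute)
})

test_that("scan absorption correction restores rotational invariance of I_o", {
  fx <- small_scan()
  corr <- correct_scan(fx$scan)
  rowtot <- apply(scan_profiles(corr), 1, sum)
  expect_lt((max(rowtot) - min(rowtot)) / mean(rowtot), 0.005)
  # raw measured totals vary more (Beer-Lambert weighting)
  raw <- apply(scan_profiles(fx$scan), 1, sum)
  expect_gt((max(raw) - min(raw)) / mean(raw),
            (max(rowtot) - min(rowtot)) / mean(rowtot))
})

test_that("background estimation picks the empty-beam frames", {
  fx <- small_scan()
  bg <- estimate_background(fx$scan, fraction = 0.02)
  # the lowest-intensity frames miss the annulus entirely: background ~ 0
  expect_lt(max(bg$intensity), 1e-8)
})
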