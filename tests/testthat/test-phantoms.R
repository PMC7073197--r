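test_that("ellipsoid-cap closed form matches Monte-Carlo voxel counting", {
  # sphere r = 1, plane 0.5 below centre: h^2 (3r - h) / (4 r^3) = 15.625%
  expect_equal(ellipsoid_fraction_below(0, 1, -0.5), 15.625)
  expect_equal(ellipsoid_fraction_below(5, 3, 5), 50)
  expect_equal(ellipsoid_fraction_below(5, 3, 1), 0)
  expect_equal(ellipsoid_fraction_below(5, 3, 9), 100)

  # independent oracle: uniform samples in the bounding box of an ellipsoid,
  # 1e7 points in chunks; agreement within 0.2 percentage points
  a <- 2; b <- 1.5; cc <- 1; z0 <- -0.4
  set.seed(123)
  inside_total <- 0; below_total <- 0
  for (chunk in 1:10) {
    n <- 1e6
    x <- stats::runif(n, -a, a)
    y <- stats::runif(n, -b, b)
    z <- stats::runif(n, -cc, cc)
    inside <- (x / a)^2 + (y / b)^2 + (z / cc)^2 <= 1
    inside_total <- inside_total + sum(inside)
    below_total <- below_total + sum(inside & z < z0)
  }
  mc <- 100 * below_total / inside_total
  expect_lt(abs(mc - ellipsoid_fraction_below(0, cc, z0)), 0.2)
})

test_that("invasion phantom is seed-deterministic and carries exact truth", {
  sp <- function() invasion_phantom_spec(
    data.frame(x = 3, y = 3, z = 4, a = 1.5, b = 1.5, c = 1.5),
    membrane_z_upper = 4, dim = c(40, 64, 64), seed = 9)
  g1 <- generate_invasion_stack(sp())
  g2 <- generate_invasion_stack(sp())
  expect_identical(g1$stack$channels, g2$stack$channels)
  expect_equal(g1$truth$fraction_below_pct, 50)
  expect_equal(g1$truth$volume_um3, 4 / 3 * pi * 1.5^3)

  # sphere wholly above the membrane
  g3 <- generate_invasion_stack(invasion_phantom_spec(
    data.frame(x = 3, y = 3, z = 5.5, a = 1.4, b = 1.4, c = 1.4),
    membrane_z_upper = 4, dim = c(40, 64, 64), seed = 2))
  expect_equal(g3$truth$fraction_below_pct, 0)
})

test_that("invasion phantom validates geometry and names offending cells", {
  expect_error(invasion_phantom_spec(
    data.frame(x = 1, y = 3, z = 4, a = 2, b = 1, c = 1),
    membrane_z_upper = 4, dim = c(40, 64, 64)), "cell 1")
  expect_error(invasion_phantom_spec(
    data.frame(x = 3, y = 3, z = 4, a = -1, b = 1, c = 1),
    membrane_z_upper = 4, dim = c(40, 64, 64)), "semi-axes")
  expect_error(invasion_phantom_spec(
    data.frame(x = 3, y = 3, z = 4, a = 1, b = 1, c = 1),
    membrane_z_upper = 4, membrane_z_lower = 5,
    dim = c(40, 64, 64)), "membrane_z_lower")
})

test_that("rendered cells respect anisotropic voxel sizes", {
  g <- generate_invasion_stack(invasion_phantom_spec(
    data.frame(x = 4, y = 3, z = 4, a = 2.5, b = 1.5, c = 1.5),
    membrane_z_upper = 4, dim = c(40, 64, 96),
    voxel_size = c(0.2, 0.1, 0.1), noise_sd = 0, psf_sigma = 0, seed = 1))
  mask <- g$stack$channels$cell > 500
  on <- which(mask, arr.ind = TRUE)
  ext_y <- diff(range(on[, 1] - 1)) * 0.1
  ext_x <- diff(range(on[, 2] - 1)) * 0.1
  ext_z <- diff(range(on[, 3] - 1)) * 0.2
  expect_lt(abs(ext_x - 5), 0.1 + 1e-9)   # within one voxel per axis
  expect_lt(abs(ext_y - 3), 0.1 + 1e-9)
  expect_lt(abs(ext_z - 3), 0.2 + 1e-9)
})

test_that("pillar phantom is deterministic and rejects ambiguous motion", {
  sp <- function(seed = 2) pillar_phantom_spec(n_rows = 3, n_cols = 3,
                                               n_frames = 4, seed = seed)
  p1 <- generate_pillar_sequence(sp())
  p2 <- generate_pillar_sequence(sp())
  expect_identical(p1$frames, p2$frames)
  expect_false(identical(p1$frames,
                         generate_pillar_sequence(sp(seed = 3))$frames))
  expect_equal(max(abs(p1$truth_displacements)), 0)

  disp <- array(0, c(9, 4, 2)); disp[5, 3, 1] <- 1.2
  expect_error(pillar_phantom_spec(n_rows = 3, n_cols = 3, n_frames = 4,
                                   displacements = disp), "pitch/2")
  disp[5, 3, 1] <- 0.425
  pp <- generate_pillar_sequence(pillar_phantom_spec(
    n_rows = 3, n_cols = 3, n_frames = 4, displacements = disp))
  expect_equal(max(pp$truth_displacements[5, , 1]), 0.425)
})

test_that("bead-trace phantom amplitudes match the programmed schedule", {
  g <- generate_bead_trace(trace_phantom_spec(
    amplitudes = seq(100, 75, length.out = 12), noise_sd = 0,
    drift_nm_s = 0, seed = 3))
  expect_equal(g$truth$amplitudes_nm[1], 100, tolerance = 1e-3)
  expect_equal(g$truth$decrease_pct, 25, tolerance = 0.1)
  g2 <- generate_bead_trace(trace_phantom_spec(
    amplitudes = 100, noise_sd = 0, drift_nm_s = 0))
  expect_equal(g2$truth$r12, 1, tolerance = 1e-9)

  t1 <- generate_bead_trace(trace_phantom_spec(seed = 4))
  t2 <- generate_bead_trace(trace_phantom_spec(seed = 4))
  expect_identical(t1$trace, t2$trace)
  expect_error(trace_phantom_spec(sample_rate_hz = 0.5), "sample rate")
})

test_that("force-curve phantom passes through zero force at contact", {
  g <- generate_force_curve(curve_phantom_spec(E_pa = 300, noise_sd_pn = 0))
  cur <- g$curve
  pre <- cur$force_nN[cur$position_um <= g$truth$contact_um]
  expect_equal(max(abs(pre)), 0)
  i <- which(cur$position_um > g$truth$contact_um)[1]
  expect_lt(cur$force_nN[i], 1e-3)
  expect_gte(max(cur$force_nN), 1)          # reaches the 1 nN set force

  # doubling E doubles the post-contact force at fixed indentation depth
  expect_equal(hertz_force(0.7, 600, 7.5), 2 * hertz_force(0.7, 300, 7.5))

  c1 <- generate_force_curve(curve_phantom_spec(300, seed = 6))
  c2 <- generate_force_curve(curve_phantom_spec(300, seed = 6))
  expect_identical(c1$curve, c2$curve)
  expect_error(generate_force_curve(curve_phantom_spec(300, z_max_um = 1.5)),
               "unreachable")
})
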