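test_that("locate_membrane picks the upper layer of a bilayer", {
  g <- generate_invasion_stack(one_cell_phantom(11, membrane_z = 8, seed = 3))
  mem <- locate_membrane(g$stack)
  expect_equal(mem$z_um, 8)                 # upper layer; lower sits at 7.2

  # single layer: make the two layers coincide up to rendering
  g2 <- generate_invasion_stack(invasion_phantom_spec(
    data.frame(x = 3, y = 3, z = 5.6, a = 1.4, b = 1.4, c = 1.4),
    membrane_z_upper = 5, membrane_z_lower = 1,
    dim = c(40, 64, 64), seed = 4))
  expect_equal(locate_membrane(g2$stack)$z_um, 5)

  blank <- image_stack(list(cell = array(0, c(8, 8, 6)),
                            membrane = array(0, c(8, 8, 6))),
                       c(0.2, 0.1, 0.1))
  expect_error(locate_membrane(blank), "not detected")
})

test_that("reconstruct_cell recovers a sphere's volume from ring contours", {
  r <- 5; dz <- 0.2
  zs <- seq(-r + dz / 2, r - dz / 2, by = dz)
  contours <- lapply(seq_along(zs), function(i) {
    rho <- sqrt(r^2 - zs[i]^2)
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    structure(list(boundary = cbind(1 + (60 + rho * 10 * cos(th)),
                                    1 + (60 + rho * 10 * sin(th))),
                   slice = i), class = "cell_contour")
  })
  # voxel 0.1 um in xy (so rho * 10 px), dz in z
  rec <- reconstruct_cell(contours, c(dz, 0.1, 0.1))
  expect_equal(rec$volume_um3, 4 / 3 * pi * r^3, tolerance = 0.02)

  # doubling dz doubles the hull volume exactly (affine scaling in z)
  rec2 <- reconstruct_cell(contours, c(2 * dz, 0.1, 0.1))
  expect_equal(rec2$volume_um3, 2 * rec$volume_um3, tolerance = 1e-9)

  expect_error(reconstruct_cell(contours[1], c(dz, 0.1, 0.1)),
               "insufficient z-extent")
})

test_that("percent_invasion handles extreme planes and symmetry exactly", {
  oct <- list(cell_id = 1,
              hull = convex_hull_3d(rbind(c(1, 0, 2), c(-1, 0, 2),
                                          c(0, 1, 2), c(0, -1, 2),
                                          c(0, 0, 3), c(0, 0, 1))),
              volume_um3 = NA, slice_range = c(1, 2))
  oct$volume_um3 <- oct$hull$volume
  class(oct) <- "cell_reconstruction"
  expect_equal(percent_invasion(oct, 0.5)$percent_invasion, 0)
  expect_equal(percent_invasion(oct, 9)$percent_invasion, 100)
  expect_equal(percent_invasion(oct, 2)$percent_invasion, 50,
               tolerance = 1e-9)
  # monotone in plane height, and complements sum to 100
  zs <- seq(0.9, 3.1, length.out = 15)
  p <- vapply(zs, function(z) percent_invasion(oct, z)$percent_invasion,
              numeric(1))
  expect_true(all(diff(p) >= -1e-12))
})

test_that("full pipeline recovers the hemisphere-on-plane case", {
  g <- generate_invasion_stack(one_cell_phantom(8, membrane_z = 8, seed = 11))
  res <- run_qpi(g$stack)
  expect_equal(nrow(res), 1L)
  expect_lt(abs(res$percent_invasion - 50), 1.5)
  expect_equal(res$membrane_z_um, 8)
  expect_equal(res$volume_um3, g$truth$volume_um3, tolerance = 0.06)
})

test_that("pipeline skips border-touching cells and empty channels", {
  # cell hugging the lateral border: legal for the generator margin but its
  # contours touch column 1 after segmentation
  g <- generate_invasion_stack(invasion_phantom_spec(
    data.frame(x = 1.55, y = 3.2, z = 8, a = 1.5, b = 1.5, c = 1.5),
    membrane_z_upper = 8, dim = c(76, 64, 64), seed = 5))
  res <- run_qpi(g$stack)
  expect_equal(nrow(res), 0L)
  expect_true(any(grepl("border", attr(res, "skipped")$reason)))

  blank <- generate_invasion_stack(one_cell_phantom(8, seed = 6))
  blank$stack$channels$cell[] <- 0
  res2 <- run_qpi(blank$stack)
  expect_equal(nrow(res2), 0L)
})

test_that("hull from ellipse outlines is available as an alternative", {
  g <- generate_invasion_stack(one_cell_phantom(8, membrane_z = 8, seed = 12))
  res <- run_qpi(g$stack, hull_source = "ellipse")
  expect_equal(nrow(res), 1L)
  expect_lt(abs(res$percent_invasion - 50), 3)
})

test_that("cumulative invaded-cell count follows the stated summation rule", {
  cc <- cumulative_invaded_count(c(2, 3), mesenteries = 1,
                                 daily_se = c(0.5, 0.5))
  expect_equal(cc$cumulative, c(2, 5))
  expect_equal(cc$cumulative_se, c(0.5, 1.0))

  cc2 <- cumulative_invaded_count(c(4, 4), mesenteries = 2)
  expect_equal(cc2$mean_per_roi, c(2, 2))

  # per-ROI counts: mean and its standard error divided by mesenteries
  cc3 <- cumulative_invaded_count(list(c(2, 4, 6), c(1, 3)), mesenteries = 2)
  expect_equal(cc3$mean_per_roi, c(2, 1))
  expect_equal(cc3$se[1], stats::sd(c(2, 4, 6)) / sqrt(3) / 2)
  expect_true(all(diff(cc3$cumulative) >= 0))

  expect_error(cumulative_invaded_count(c(1, 2), mesenteries = 0), ">= 1")
})
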