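test_that("hull of known solids has exact volume, area and facet structure", {
  cube <- convex_hull_3d(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(cube$volume, 1)
  expect_equal(cube$area, 6)
  expect_equal(nrow(cube$vertices), 8L)

  # regular tetrahedron with unit edge: V = 1/(6 sqrt(2))
  tet <- convex_hull_3d(rbind(c(1, 1, 1), c(1, -1, -1),
                              c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8))
  expect_equal(tet$volume, 1 / (6 * sqrt(2)), tolerance = 1e-12)

  # interior points do not change the hull
  cube2 <- convex_hull_3d(rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                                matrix(stats::runif(30, 0.2, 0.8), ncol = 3)))
  expect_equal(cube2$volume, 1)
  expect_equal(nrow(cube2$vertices), 8L)
})

test_that("every input point lies inside the hull (random clouds)", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(stats::rnorm(150 * 3), ncol = 3)
    h <- convex_hull_3d(pts)
    v <- h$vertices
    for (i in seq_len(nrow(h$faces))) {
      f <- h$faces[i, ]
      a <- v[f[1L], ]
      n <- mechanoinvade:::.cross3(v[f[2L], ] - a, v[f[3L], ] - a)
      expect_true(all(pts %*% n - sum(n * a) <= 1e-8))
    }
  }
})

test_that("hull volume is invariant under rigid rotation", {
  set.seed(42)
  pts <- matrix(stats::rnorm(120 * 3), ncol = 3)
  v0 <- convex_hull_3d(pts)$volume
  qr_rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  v1 <- convex_hull_3d(pts %*% qr_rot)$volume
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  expect_error(convex_hull_3d(matrix(stats::rnorm(6), ncol = 3)), "4 distinct")
  flat <- cbind(matrix(stats::rnorm(20), ncol = 2), 0)
  expect_error(convex_hull_3d(flat), "degenerate")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(convex_hull_3d(line), "degenerate")
})

test_that("clipped volume below a plane is exact on analytic cases", {
  cube <- convex_hull_3d(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(hull_volume_below(cube, 0.25), 0.25, tolerance = 1e-12)
  expect_equal(hull_volume_below(cube, -1), 0)
  expect_equal(hull_volume_below(cube, 2), 1)

  # regular octahedron centred on the plane: exactly half below
  oct <- convex_hull_3d(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  expect_equal(hull_volume_below(oct, 0) / oct$volume, 0.5, tolerance = 1e-12)

  # spherical cap: h^2 (3 - h) / 4 of the sphere volume
  hs <- convex_hull_3d(sphere_points(3000, seed = 7))
  frac <- hull_volume_below(hs, -0.5) / hs$volume
  expect_equal(100 * frac, 15.625, tolerance = 0.01)
})

test_that("below and above fractions sum to the whole volume exactly", {
  for (seed in 1:4) {
    h <- random_hull(seed)
    z0 <- mean(range(h$vertices[, 3]))
    below <- hull_volume_below(h, z0)
    # flip z to measure the complementary part with the same code path
    hf <- convex_hull_3d(h$vertices %*% diag(c(1, 1, -1)))
    above <- hull_volume_below(hf, -z0)
    expect_equal(below + above, h$volume, tolerance = 1e-9 * h$volume)
  }
})

test_that("clipped volume is monotone non-decreasing in plane height", {
  h <- random_hull(11)
  zs <- seq(min(h$vertices[, 3]) - 0.1, max(h$vertices[, 3]) + 0.1,
            length.out = 40)
  vols <- vapply(zs, function(z) hull_volume_below(h, z), numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  expect_equal(vols[1], 0)
  expect_equal(vols[length(vols)], h$volume)
})

test_that("tetrahedral clipping agrees with the Monte-Carlo oracle", {
  set.seed(99)
  for (seed in c(3, 17, 29)) {
    h <- random_hull(seed)
    z0 <- stats::quantile(h$vertices[, 3], 0.4)
    exact <- 100 * hull_volume_below(h, z0) / h$volume
    mc <- mc_fraction_below(h, z0, n = 2e5)
    expect_lt(abs(exact - mc$fraction_below), 1)
    expect_equal(mc$volume, h$volume, tolerance = 0.05)
  }
})
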