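# shared fixtures, all built in code

# rasterised circle boundary (unique integer chain, ordered by angle)
raster_circle <- function(cy, cx, r, n = 400L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  unique(round(cbind(cy + r * cos(th), cx + r * sin(th))))
}

# Hausdorff distance from a chain to the polygon through its subset
chain_polygon_hausdorff <- function(chain, poly) {
  segdist <- function(p, a, b) {
    ab <- b - a
    t <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  np <- nrow(poly)
  max(vapply(seq_len(nrow(chain)), function(i) {
    min(vapply(seq_len(np), function(j)
      segdist(chain[i, ], poly[j, ], poly[(j %% np) + 1L, ]), numeric(1L)))
  }, numeric(1L)))
}

# random convex hull from a Gaussian cloud
random_hull <- function(seed, n = 60L) {
  set.seed(seed)
  convex_hull_3d(matrix(stats::rnorm(n * 3L), ncol = 3L))
}

# dense point sampling of a sphere surface (all points on the hull)
sphere_points <- function(n, r = 1, seed = 1L) {
  set.seed(seed)
  p <- matrix(stats::rnorm(n * 3L), ncol = 3L)
  r * p / sqrt(rowSums(p^2))
}

# single-ellipsoid invasion phantom centred laterally in a default stack
one_cell_phantom <- function(z_center, membrane_z = 8, a = 3, b = 3, c = 3,
                             seed = 1L, ...) {
  invasion_phantom_spec(
    cells = data.frame(x = 6.4, y = 6.4, z = z_center, a = a, b = b, c = c),
    membrane_z_upper = membrane_z, dim = c(76L, 128L, 128L), seed = seed, ...)
}
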