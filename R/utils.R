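# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur of a 3D array [y, x, z] with per-axis sigma in
# voxels; sigma 0 skips the axis. Edge kernels are renormalised (no padding
# artefacts).
.gauss_blur3 <- function(a, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    n <- dim(a)[axis]
    half <- max(1L, ceiling(3 * s))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * s^2))
      w * (abs(i - j) <= half)
    })
    K <- sweep(K, 2L, colSums(K), "/")
    perm <- switch(axis, c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, ncol = n) %*% K
    a <- aperm(array(m, dp), order(perm))
  }
  a
}

# single stat summary used by print methods
.fmt_um <- function(x) sprintf("%.3g um", x)
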