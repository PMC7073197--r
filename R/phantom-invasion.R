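#' Specification of a synthetic basement-membrane invasion stack
#'
#' Describes a two-channel confocal z-stack phantom: ellipsoidal "cells" in a
#' cell (actin) channel and a laminin-like membrane rendered as two
#' Gaussian-profile horizontal layers (a bilayer) in a membrane channel. The
#' phantom carries analytic ground truth — every cell's volume and the exact
#' fraction of its volume below the upper membrane layer — so the volumetric
#' invasion pipeline can be validated end-to-end.
#'
#' The z convention everywhere in this package: slice 1 is the lowest physical
#' z (the substrate side, below the membrane); cells sit above the membrane
#' and invade toward decreasing z. "Percent invasion" of a cell is the percent
#' of its volume with z below the *upper* membrane layer.
#'
#' @param cells data.frame with one row per cell and columns `x`, `y`, `z`
#'   (centre, um), `a`, `b`, `c` (semi-axes along x, y, z, um) and optionally
#'   `intensity` (default 1000).
#' @param membrane_z_upper z of the upper laminin layer (um).
#' @param membrane_z_lower z of the lower layer (um); default 0.8 um below the
#'   upper one.
#' @param dim stack shape `c(nz, ny, nx)`.
#' @param voxel_size `c(dz, dy, dx)` in um; dz defaults to 0.2 um (the
#'   acquisition z-step).
#' @param noise_sd additive Gaussian noise SD, intensity units (clipped at 0).
#' @param psf_sigma isotropic Gaussian PSF sigma in um (0 = no blur).
#' @param membrane_intensity peak intensity of each membrane layer.
#' @param membrane_sigma_z axial Gaussian thickness of each layer (um).
#' @param seed integer; fully determines the generated voxels.
#' @return An object of class `invasion_phantom_spec`.
#' @seealso [generate_invasion_stack()], [ellipsoid_fraction_below()]
#' @export
invasion_phantom_spec <- function(cells,
                                  membrane_z_upper,
                                  membrane_z_lower = membrane_z_upper - 0.8,
                                  dim = c(76L, 128L, 128L),
                                  voxel_size = c(0.2, 0.1, 0.1),
                                  noise_sd = 30,
                                  psf_sigma = 0.2,
                                  membrane_intensity = 1000,
                                  membrane_sigma_z = 0.2,
                                  seed = 1L) {
  cells <- as.data.frame(cells)
  need <- c("x", "y", "z", "a", "b", "c")
  if (!all(need %in% names(cells)))
    stop("'cells' needs columns ", paste(need, collapse = ", "))
  if (is.null(cells$intensity)) cells$intensity <- 1000
  if (any(cells[, c("a", "b", "c")] <= 0)) stop("semi-axes must be > 0")
  if (!(membrane_z_lower < membrane_z_upper))
    stop("membrane_z_lower must be below membrane_z_upper")
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            noise_sd >= 0, psf_sigma >= 0, membrane_sigma_z > 0)
  extent <- (dim - 1L) * voxel_size        # (z, y, x) physical extent
  for (i in seq_len(nrow(cells))) {
    lo <- c(cells$z[i] - cells$c[i], cells$y[i] - cells$b[i],
            cells$x[i] - cells$a[i])
    hi <- c(cells$z[i] + cells$c[i], cells$y[i] + cells$b[i],
            cells$x[i] + cells$a[i])
    if (any(lo < 0) || any(hi > extent))
      stop("cell ", i, " extends outside the stack bounds")
  }
  if (membrane_z_upper > extent[1L] || membrane_z_lower < 0)
    stop("membrane layers must lie inside the stack z-range")
  structure(list(cells = cells, membrane_z_upper = membrane_z_upper,
                 membrane_z_lower = membrane_z_lower, dim = dim,
                 voxel_size = voxel_size, noise_sd = noise_sd,
                 psf_sigma = psf_sigma,
                 membrane_intensity = membrane_intensity,
                 membrane_sigma_z = membrane_sigma_z,
                 seed = as.integer(seed)),
            class = "invasion_phantom_spec")
}

#' Fraction of an ellipsoid's volume below a horizontal plane
#'
#' Closed-form ellipsoid-cap formula. An ellipsoid with z semi-axis `c`
#' centred at `z_center` maps affinely onto the unit sphere, so the fraction
#' below `z = z0` is the unit-sphere cap fraction `h^2 (3 - h) / 4` with
#' `h = clamp((z0 - z_center) / c, -1, 1) + 1`. This is the analytic ground
#' truth against which hull-based invasion estimates are judged.
#'
#' @param z_center ellipsoid centre z (um).
#' @param c_semi semi-axis along z (um).
#' @param z0 plane height (um).
#' @return fraction below the plane, in percent (0-100). Vectorised.
#' @examples
#' ellipsoid_fraction_below(0, 1, 0)      # 50
#' ellipsoid_fraction_below(0, 1, -0.5)   # 15.625
#' @export
ellipsoid_fraction_below <- function(z_center, c_semi, z0) {
  stopifnot(all(c_semi > 0))
  t <- pmin(pmax((z0 - z_center) / c_semi, -1), 1)
  h <- t + 1
  100 * h^2 * (3 - h) / 4
}

#' Generate a synthetic invasion z-stack with analytic ground truth
#'
#' Renders the phantom described by an [invasion_phantom_spec()]: each
#' ellipsoid is painted into the cell channel (voxel centre inside the
#' ellipsoid), the membrane bilayer into the membrane channel as two Gaussian
#' z-profiles, both channels are blurred with the isotropic Gaussian PSF and
#' Gaussian noise (clipped at zero) is added. Identical specs (seed included)
#' produce bit-identical stacks.
#'
#' @param spec an [invasion_phantom_spec()].
#' @return list with `stack` (an [image_stack()] with channels `cell` and
#'   `membrane`) and `truth` (data.frame: `cell`, `volume_um3`,
#'   `fraction_below_pct` from the ellipsoid-cap closed form).
#' @export
generate_invasion_stack <- function(spec) {
  stopifnot(inherits(spec, "invasion_phantom_spec"))
  nz <- spec$dim[1L]; ny <- spec$dim[2L]; nx <- spec$dim[3L]
  dz <- spec$voxel_size[1L]; dy <- spec$voxel_size[2L]; dx <- spec$voxel_size[3L]
  zs <- (seq_len(nz) - 1L) * dz
  ys <- (seq_len(ny) - 1L) * dy
  xs <- (seq_len(nx) - 1L) * dx

  cell_ch <- array(0, c(ny, nx, nz))
  for (i in seq_len(nrow(spec$cells))) {
    ci <- spec$cells[i, ]
    iz <- which(abs(zs - ci$z) < ci$c)
    for (k in iz) {
      f <- sqrt(1 - ((zs[k] - ci$z) / ci$c)^2)
      ry <- ci$b * f; rx <- ci$a * f
      m <- outer(((ys - ci$y) / ry)^2, ((xs - ci$x) / rx)^2, "+") <= 1
      cell_ch[, , k] <- cell_ch[, , k] + ci$intensity * m
    }
  }
  prof <- spec$membrane_intensity *
    (exp(-(zs - spec$membrane_z_upper)^2 / (2 * spec$membrane_sigma_z^2)) +
     exp(-(zs - spec$membrane_z_lower)^2 / (2 * spec$membrane_sigma_z^2)))
  mem_ch <- array(rep(prof, each = ny * nx), c(ny, nx, nz))

  if (spec$psf_sigma > 0) {
    sig_vox <- spec$psf_sigma / c(dy, dx, dz)
    cell_ch <- .gauss_blur3(cell_ch, sig_vox)
    mem_ch <- .gauss_blur3(mem_ch, sig_vox)
  }
  if (spec$noise_sd > 0) {
    .with_seed(spec$seed, {
      cell_ch <- cell_ch + stats::rnorm(length(cell_ch), 0, spec$noise_sd)
      mem_ch <- mem_ch + stats::rnorm(length(mem_ch), 0, spec$noise_sd)
    })
    cell_ch[cell_ch < 0] <- 0
    mem_ch[mem_ch < 0] <- 0
  }
  stack <- image_stack(list(cell = cell_ch, membrane = mem_ch),
                       voxel_size = spec$voxel_size)
  truth <- data.frame(
    cell = seq_len(nrow(spec$cells)),
    volume_um3 = 4 / 3 * pi * spec$cells$a * spec$cells$b * spec$cells$c,
    fraction_below_pct = ellipsoid_fraction_below(spec$cells$z, spec$cells$c,
                                                  spec$membrane_z_upper))
  list(stack = stack, truth = truth)
}
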