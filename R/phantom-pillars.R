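#' Specification of a synthetic micropillar time-lapse sequence
#'
#' Describes a bright-field-like time-lapse of a regular pillar lattice: each
#' pillar top appears as a Gaussian spot whose centre moves by a prescribed
#' per-pillar displacement plus a global stage drift. Displacements and drift
#' are the analytic ground truth for the tracking pipeline.
#'
#' @param n_rows,n_cols lattice size (pillar count per axis).
#' @param pitch lattice spacing, um.
#' @param spot_sigma Gaussian spot sigma, um.
#' @param pixel_size camera pixel size, um.
#' @param n_frames number of frames.
#' @param frame_interval_s seconds between frames (default 1 s).
#' @param displacements either `NULL` (all pillars static) or a numeric array
#'   `[pillar, frame, 2]` of (y, x) displacements in um, pillar index running
#'   row-major over the lattice.
#' @param drift matrix `[frame, 2]` of global (y, x) stage drift in um, or
#'   `NULL` for none.
#' @param amplitude peak spot intensity.
#' @param noise_sd additive Gaussian camera noise SD (intensity units).
#' @param margin border between the outermost pillars and the image edge, um.
#' @param seed integer RNG seed; fully determines the frames.
#' @return An object of class `pillar_phantom_spec`.
#' @seealso [generate_pillar_sequence()]
#' @export
pillar_phantom_spec <- function(n_rows = 8L, n_cols = 8L, pitch = 2,
                                spot_sigma = 0.3, pixel_size = 0.1,
                                n_frames = 60L, frame_interval_s = 1,
                                displacements = NULL, drift = NULL,
                                amplitude = 1000, noise_sd = 20,
                                margin = 2, seed = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_frames <- as.integer(n_frames)
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_frames >= 1L, pitch > 0,
            spot_sigma > 0, pixel_size > 0, frame_interval_s > 0,
            amplitude > 0, noise_sd >= 0, margin >= 0)
  np <- n_rows * n_cols
  if (is.null(displacements))
    displacements <- array(0, c(np, n_frames, 2L))
  displacements <- unname(displacements)
  if (!identical(dim(displacements), c(np, n_frames, 2L)))
    stop("'displacements' must be a [", np, ", ", n_frames, ", 2] array")
  if (max(abs(displacements)) > pitch / 2)
    stop("a displacement exceeds pitch/2 (", pitch / 2,
         " um); pillar identity would be ambiguous")
  if (is.null(drift)) drift <- matrix(0, n_frames, 2L)
  drift <- unname(as.matrix(drift))
  if (!identical(dim(drift), c(n_frames, 2L)))
    stop("'drift' must be a [", n_frames, ", 2] matrix")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 spot_sigma = spot_sigma, pixel_size = pixel_size,
                 n_frames = n_frames, frame_interval_s = frame_interval_s,
                 displacements = displacements, drift = drift,
                 amplitude = amplitude, noise_sd = noise_sd,
                 margin = margin, seed = as.integer(seed)),
            class = "pillar_phantom_spec")
}

#' Generate a synthetic pillar time-lapse with ground-truth displacements
#'
#' Renders every frame of the phantom described by a [pillar_phantom_spec()]:
#' Gaussian spots at rest position + per-pillar displacement + global drift,
#' plus clipped Gaussian camera noise. Identical specs give bit-identical
#' frames.
#'
#' @param spec a [pillar_phantom_spec()].
#' @return list with `frames` (array `[y, x, frame]`, intensities),
#'   `rest_positions` (matrix `[pillar, (y, x)]`, um), `truth_displacements`
#'   (the spec's `[pillar, frame, 2]` array, um), `drift` (`[frame, 2]`, um)
#'   and `pixel_size` (um).
#' @export
generate_pillar_sequence <- function(spec) {
  stopifnot(inherits(spec, "pillar_phantom_spec"))
  rest <- as.matrix(expand.grid(
    y = spec$margin + (seq_len(spec$n_rows) - 1L) * spec$pitch,
    x = spec$margin + (seq_len(spec$n_cols) - 1L) * spec$pitch))
  np <- nrow(rest)
  ny <- ceiling((max(rest[, 1L]) + spec$margin) / spec$pixel_size) + 1L
  nx <- ceiling((max(rest[, 2L]) + spec$margin) / spec$pixel_size) + 1L
  ys <- (seq_len(ny) - 1L) * spec$pixel_size
  xs <- (seq_len(nx) - 1L) * spec$pixel_size
  half <- ceiling(4 * spec$spot_sigma / spec$pixel_size)
  frames <- array(0, c(ny, nx, spec$n_frames))
  for (fi in seq_len(spec$n_frames)) {
    img <- matrix(0, ny, nx)
    for (p in seq_len(np)) {
      cy <- rest[p, 1L] + spec$displacements[p, fi, 1L] + spec$drift[fi, 1L]
      cx <- rest[p, 2L] + spec$displacements[p, fi, 2L] + spec$drift[fi, 2L]
      i0 <- max(1L, round(cy / spec$pixel_size) + 1L - half)
      i1 <- min(ny, round(cy / spec$pixel_size) + 1L + half)
      j0 <- max(1L, round(cx / spec$pixel_size) + 1L - half)
      j1 <- min(nx, round(cx / spec$pixel_size) + 1L + half)
      gy <- exp(-(ys[i0:i1] - cy)^2 / (2 * spec$spot_sigma^2))
      gx <- exp(-(xs[j0:j1] - cx)^2 / (2 * spec$spot_sigma^2))
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + spec$amplitude * outer(gy, gx)
    }
    frames[, , fi] <- img
  }
  if (spec$noise_sd > 0) {
    .with_seed(spec$seed, {
      frames <- frames + stats::rnorm(length(frames), 0, spec$noise_sd)
    })
    frames[frames < 0] <- 0
  }
  list(frames = frames, rest_positions = rest,
       truth_displacements = spec$displacements, drift = spec$drift,
       pixel_size = spec$pixel_size,
       frame_interval_s = spec$frame_interval_s)
}
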