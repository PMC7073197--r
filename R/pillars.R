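#' Lateral spring constant of an elastic micropillar
#'
#' Models the pillar as an Euler-Bernoulli cantilever loaded laterally at its
#' tip: `k = 3 E I / L^3` with the second moment of area of a circular cross
#' section `I = pi d^4 / 64`. Traction force is then displacement times `k`.
#'
#' @param E_pa elastic modulus of the pillar material, Pa.
#' @param height_um pillar height L, um.
#' @param diameter_um pillar diameter d, um.
#' @return spring constant in nN/um.
#' @examples
#' compute_spring_constant(2e6, 5, 1)  # 2.356 nN/um (PDMS micropillar)
#' @export
compute_spring_constant <- function(E_pa, height_um, diameter_um) {
  if (any(c(E_pa, height_um, diameter_um) <= 0))
    stop("E, height and diameter must all be positive")
  I_m4 <- pi * (diameter_um * 1e-6)^4 / 64
  k_N_m <- 3 * E_pa * I_m4 / (height_um * 1e-6)^3
  k_N_m * 1000                              # 1 N/m = 1000 nN/um
}

# profile likelihood Gaussian spot fit on a window: amplitude and offset are
# solved linearly for each candidate (cy, cx, log sigma); Nelder-Mead on the
# remaining 3 parameters. Returns centre in um plus a convergence flag.
.fit_spot <- function(img, ys, xs, cy0, cx0, sigma0) {
  yy <- rep(ys, times = length(xs))
  xx <- rep(xs, each = length(ys))
  I <- as.vector(img)
  rssf <- function(p) {
    g <- exp(-((yy - p[1L])^2 + (xx - p[2L])^2) / (2 * exp(2 * p[3L])))
    vg <- stats::var(g)
    if (vg < 1e-12) return(sum((I - mean(I))^2))
    A <- stats::cov(g, I) / vg
    b <- mean(I) - A * mean(g)
    sum((I - A * g - b)^2)
  }
  fit <- tryCatch(
    stats::optim(c(cy0, cx0, log(sigma0)), rssf,
                 control = list(maxit = 400, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, cy = cy0, cx = cx0))
  inside <- fit$par[1L] >= min(ys) && fit$par[1L] <= max(ys) &&
    fit$par[2L] >= min(xs) && fit$par[2L] <= max(xs)
  list(ok = fit$convergence == 0 && inside,
       cy = fit$par[1L], cx = fit$par[2L])
}

#' Detect pillar rest positions in the first frame
#'
#' Finds the regular lattice of pillar tops: Gaussian smoothing, a threshold
#' halfway between background and peak intensity, local maxima separated by
#' at least half the expected pitch, then subpixel refinement of every
#' candidate by a 2D Gaussian fit. Lattice completeness (found vs expected
#' from the bounding box of detections) is reported and a warning emitted
#' when pillars are missing.
#'
#' @param frame 2D intensity matrix `[y, x]`.
#' @param pitch_um expected lattice pitch, um.
#' @param pixel_size_um camera pixel size, um.
#' @return matrix `[pillar, c(y, x)]` of rest positions in um, ordered
#'   row-major; attribute `completeness` = found / expected.
#' @export
detect_pillars <- function(frame, pitch_um, pixel_size_um) {
  stopifnot(is.matrix(frame), pitch_um > 0, pixel_size_um > 0)
  sm <- EBImage::gblur(frame, sigma = max(1, 0.1 * pitch_um / pixel_size_um))
  thr <- (stats::quantile(sm, 0.05) + max(sm)) / 2
  half <- max(1L, floor(pitch_um / (2 * pixel_size_um)))
  ny <- nrow(sm); nx <- ncol(sm)
  peaks <- which(sm > thr, arr.ind = TRUE)
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    r <- peaks[i, 1L]; c0 <- peaks[i, 2L]
    w <- sm[max(1L, r - half):min(ny, r + half),
            max(1L, c0 - half):min(nx, c0 + half)]
    keep[i] <- sm[r, c0] == max(w)
  }
  peaks <- peaks[keep, , drop = FALSE]
  # collapse plateau duplicates closer than half a pitch
  if (nrow(peaks) > 1L) {
    ord <- order(peaks[, 1L], peaks[, 2L])
    peaks <- peaks[ord, , drop = FALSE]
    sel <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks) - 1L)) {
      if (!sel[i]) next
      d <- sqrt(rowSums((peaks[-seq_len(i), , drop = FALSE] -
                         matrix(peaks[i, ], nrow(peaks) - i, 2L,
                                byrow = TRUE))^2))
      sel[i + which(d < half)] <- FALSE
    }
    peaks <- peaks[sel, , drop = FALSE]
  }
  if (nrow(peaks) < 4L)
    stop("fewer than 4 pillars detected; not a pillar lattice")
  halfw <- max(2L, round(pitch_um / (3 * pixel_size_um)))
  pos <- matrix(NA_real_, nrow(peaks), 2L, dimnames = list(NULL, c("y", "x")))
  for (i in seq_len(nrow(peaks))) {
    r <- peaks[i, 1L]; c0 <- peaks[i, 2L]
    ri <- max(1L, r - halfw):min(ny, r + halfw)
    ci <- max(1L, c0 - halfw):min(nx, c0 + halfw)
    f <- .fit_spot(frame[ri, ci], (ri - 1L) * pixel_size_um,
                   (ci - 1L) * pixel_size_um,
                   (r - 1L) * pixel_size_um, (c0 - 1L) * pixel_size_um,
                   0.15 * pitch_um)
    pos[i, ] <- c(f$cy, f$cx)
  }
  pos <- pos[order(round(pos[, 1L] / pitch_um), pos[, 2L]), , drop = FALSE]
  n_y <- length(unique(round(pos[, 1L] / pitch_um)))
  n_x <- length(unique(round(pos[, 2L] / pitch_um)))
  expected <- n_y * n_x
  completeness <- nrow(pos) / expected
  if (completeness < 1)
    warning(sprintf("lattice incomplete: %d of %d expected pillars found",
                    nrow(pos), expected))
  attr(pos, "completeness") <- completeness
  pos
}

#' Track pillar centres across all frames
#'
#' Follows every pillar through the time-lapse with a subpixel 2D Gaussian
#' fit over a window centred on the pillar's position in the previous frame
#' (window width 2/3 of the pitch). The frame-1 fitted position is taken as
#' the zero-force rest position; displacement in frame f is the fitted centre
#' minus that rest position. A pillar whose fit diverges or walks out of its
#' window is flagged (its remaining frames revert to a plain intensity
#' centroid) rather than aborting the whole set.
#'
#' @param frames array `[y, x, frame]`.
#' @param rest_positions matrix `[pillar, c(y, x)]` in um, e.g. from
#'   [detect_pillars()].
#' @param pixel_size_um camera pixel size, um.
#' @param pitch_um lattice pitch, um (sets the tracking window).
#' @param frame_interval_s seconds between frames (metadata).
#' @return An object of class `pillar_tracks`: list with `centers`
#'   (`[pillar, frame, 2]`, um), `displacements` (same shape, um, relative to
#'   frame 1), `rest_positions`, `flagged` (logical per pillar), `drift`
#'   (`[frame, 2]`, zeros until [correct_drift()]), `pixel_size_um`,
#'   `frame_interval_s`.
#' @export
track_pillars <- function(frames, rest_positions, pixel_size_um, pitch_um,
                          frame_interval_s = 1) {
  stopifnot(length(dim(frames)) == 3L, pixel_size_um > 0, pitch_um > 0)
  np <- nrow(rest_positions); nf <- dim(frames)[3L]
  ny <- dim(frames)[1L]; nx <- dim(frames)[2L]
  halfw <- max(2L, round(pitch_um / (3 * pixel_size_um)))
  sigma0 <- 0.15 * pitch_um
  centers <- array(NA_real_, c(np, nf, 2L))
  flagged <- logical(np)
  for (p in seq_len(np)) {
    prev <- rest_positions[p, ]
    for (f in seq_len(nf)) {
      r <- round(prev[1L] / pixel_size_um) + 1L
      c0 <- round(prev[2L] / pixel_size_um) + 1L
      ri <- max(1L, r - halfw):min(ny, r + halfw)
      ci <- max(1L, c0 - halfw):min(nx, c0 + halfw)
      win <- frames[ri, ci, f]
      fit <- .fit_spot(win, (ri - 1L) * pixel_size_um,
                       (ci - 1L) * pixel_size_um, prev[1L], prev[2L], sigma0)
      if (!fit$ok) {
        flagged[p] <- TRUE
        w <- win - min(win)
        cy <- sum(w * ((ri - 1L) * pixel_size_um)) / sum(w)
        cx <- sum(t(w) * ((ci - 1L) * pixel_size_um)) / sum(w)
        fit <- list(cy = cy, cx = cx)
      }
      centers[p, f, ] <- c(fit$cy, fit$cx)
      prev <- c(fit$cy, fit$cx)
    }
  }
  disp <- centers
  disp[, , 1L] <- centers[, , 1L] - centers[, 1L, 1L]
  disp[, , 2L] <- centers[, , 2L] - centers[, 1L, 2L]
  structure(list(centers = centers, displacements = disp,
                 rest_positions = rest_positions, flagged = flagged,
                 drift = matrix(0, nf, 2L), drift_corrected = FALSE,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "pillar_tracks")
}

#' @export
print.pillar_tracks <- function(x, ...) {
  d <- dim(x$centers)
  cat(sprintf("pillar_tracks: %d pillars x %d frames%s\n", d[1L], d[2L],
              if (x$drift_corrected) " (drift-corrected)" else ""))
  pk <- apply(sqrt(x$displacements[, , 1L]^2 + x$displacements[, , 2L]^2),
              1L, max)
  cat(sprintf("  peak |displacement|: median %.3g um, max %.3g um; %d flagged\n",
              stats::median(pk), max(pk), sum(x$flagged)))
  invisible(x)
}

#' Correct stage drift using cell-free reference pillars
#'
#' Estimates per-frame stage drift as the mean (or median) displacement of a
#' set of reference pillars picked in a cell-free region, and subtracts it
#' from every pillar's displacement. After correction the reference pillars'
#' displacements are ~0 by construction.
#'
#' @param tracks a [track_pillars()] result.
#' @param reference_ids integer indices of the reference pillars.
#' @param estimator `"mean"` (default) or `"median"` across reference
#'   pillars.
#' @param contamination_tol_um warn when any reference pillar still moves
#'   more than this after correction (suggesting it was under load).
#' @return the `pillar_tracks` with corrected `displacements` and the
#'   estimated `drift` filled in.
#' @export
correct_drift <- function(tracks, reference_ids,
                          estimator = c("mean", "median"),
                          contamination_tol_um = 0.05) {
  stopifnot(inherits(tracks, "pillar_tracks"))
  estimator <- match.arg(estimator)
  np <- dim(tracks$displacements)[1L]
  reference_ids <- unique(as.integer(reference_ids))
  if (length(reference_ids) == 0L) stop("empty reference pillar set")
  if (any(reference_ids < 1L | reference_ids > np))
    stop("reference ids out of range")
  if (length(reference_ids) < 3L)
    warning("fewer than 3 reference pillars; drift estimate will be noisy")
  est <- if (estimator == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  nf <- dim(tracks$displacements)[2L]
  drift <- t(vapply(seq_len(nf), function(f)
    est(matrix(tracks$displacements[reference_ids, f, ], ncol = 2L)),
    numeric(2L)))
  disp <- tracks$displacements
  disp[, , 1L] <- sweep(disp[, , 1L], 2L, drift[, 1L])
  disp[, , 2L] <- sweep(disp[, , 2L], 2L, drift[, 2L])
  resid <- sqrt(disp[reference_ids, , 1L, drop = FALSE]^2 +
                disp[reference_ids, , 2L, drop = FALSE]^2)
  if (max(resid) > contamination_tol_um)
    warning(sprintf(
      "a reference pillar moves %.3g um after correction; the reference set may contain loaded pillars",
      max(resid)))
  tracks$displacements <- disp
  tracks$drift <- drift
  tracks$drift_corrected <- TRUE
  tracks
}

#' Traction forces and per-pillar peak summary
#'
#' Converts displacements to forces (`|F| = k |displacement|` per frame),
#' takes each pillar's maximum over frames as its peak force, and aggregates
#' the peaks of the pillars under the cell. The default aggregate is the mean
#' of per-pillar peak forces; `aggregate = "peak_of_means"` instead takes the
#' maximum over frames of the per-frame mean force.
#'
#' @param tracks a drift-corrected [pillar_tracks] (a warning is emitted if
#'   [correct_drift()] has not been applied).
#' @param k_nN_um pillar spring constant, nN/um (see
#'   [compute_spring_constant()]).
#' @param cell_pillars optional integer indices of the pillars under the
#'   cell; default all pillars.
#' @param aggregate `"mean_of_peaks"` (default) or `"peak_of_means"`.
#' @return An object of class `force_summary`: list with `forces`
#'   (`[pillar, frame]` force magnitudes, nN), `peaks` (per-pillar peak force,
#'   nN), `cell_force_nN` (the aggregate), `positions` (pillar rest
#'   positions, um), `aggregate`. Has `print` and `plot` (peak-force heat
#'   map) methods.
#' @export
forces_and_summary <- function(tracks, k_nN_um, cell_pillars = NULL,
                               aggregate = c("mean_of_peaks",
                                             "peak_of_means")) {
  stopifnot(inherits(tracks, "pillar_tracks"))
  aggregate <- match.arg(aggregate)
  if (k_nN_um <= 0) stop("spring constant must be positive")
  if (!tracks$drift_corrected)
    warning("tracks are not drift-corrected; forces include stage drift")
  mag <- sqrt(tracks$displacements[, , 1L]^2 + tracks$displacements[, , 2L]^2)
  forces <- k_nN_um * mag
  peaks <- apply(forces, 1L, max)
  if (is.null(cell_pillars)) cell_pillars <- seq_along(peaks)
  cell_force <- if (aggregate == "mean_of_peaks")
    mean(peaks[cell_pillars])
  else
    max(colMeans(forces[cell_pillars, , drop = FALSE]))
  structure(list(forces = forces, peaks = peaks,
                 cell_force_nN = cell_force, cell_pillars = cell_pillars,
                 positions = tracks$rest_positions, aggregate = aggregate,
                 k_nN_um = k_nN_um),
            class = "force_summary")
}

#' @export
print.force_summary <- function(x, ...) {
  cat(sprintf("force_summary: %d pillars, k = %.3g nN/um\n",
              length(x$peaks), x$k_nN_um))
  cat(sprintf("  per-pillar peak force: median %.3g nN, max %.3g nN\n",
              stats::median(x$peaks), max(x$peaks)))
  cat(sprintf("  cell force (%s over %d pillars): %.3g nN\n",
              x$aggregate, length(x$cell_pillars), x$cell_force_nN))
  invisible(x)
}

#' @rdname forces_and_summary
#' @param x a `force_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.force_summary <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "Inferno")
  col <- pal[cut(x$peaks, 64, labels = FALSE, include.lowest = TRUE)]
  graphics::plot(x$positions[, 2L], x$positions[, 1L], pch = 15, cex = 2,
                 col = col, xlab = "x (um)", ylab = "y (um)",
                 main = "per-pillar peak traction force (nN)",
                 ylim = rev(range(x$positions[, 1L])), asp = 1, ...)
  invisible(x)
}
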