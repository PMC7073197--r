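#' Locate the upper membrane layer along z
#'
#' Computes the per-slice mean intensity profile of the membrane channel and
#' returns the highest-z local maximum that exceeds background + `snr` robust
#' SDs, where background and SD are the median and MAD of the profile (most
#' slices contain no membrane, so the profile is background-dominated). With
#' a bilayer both layers qualify and the higher-z one — the upper laminin
#' layer, the one cells must breach first — is returned. Equal-height ties
#' resolve to the higher z.
#'
#' @param stack an [image_stack()].
#' @param channel membrane channel name (default `"membrane"`).
#' @param snr detection threshold in robust SDs above background.
#' @return An object of class `membrane_plane`: list with `z_um`, `slice`,
#'   `score` (peak SNR), and the `profile` used.
#' @export
locate_membrane <- function(stack, channel = "membrane", snr = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop("no channel named '", channel, "' in the stack")
  prof <- apply(stack$channels[[channel]], 3L, mean)
  bg <- stats::median(prof)
  s <- stats::mad(prof)
  if (s == 0) s <- stats::sd(prof)
  if (!is.finite(s) || s == 0) stop("membrane not detected: flat profile")
  nz <- length(prof)
  is_max <- vapply(seq_len(nz), function(i) {
    lo <- if (i > 1L) prof[i] >= prof[i - 1L] else TRUE
    hi <- if (i < nz) prof[i] >= prof[i + 1L] else TRUE
    lo && hi
  }, logical(1L))
  cand <- which(is_max & prof > bg + snr * s)
  if (length(cand) == 0L) stop("membrane not detected")
  peak <- max(cand)                          # ties and bilayer: upper wins
  structure(list(z_um = (peak - 1L) * stack$voxel_size[1L], slice = peak,
                 score = (prof[peak] - bg) / s, profile = prof),
            class = "membrane_plane")
}

#' @export
print.membrane_plane <- function(x, ...) {
  cat(sprintf("membrane_plane: upper layer at z = %.3g um (slice %d, SNR %.3g)\n",
              x$z_um, x$slice, x$score))
  invisible(x)
}

#' Reconstruct a cell as a 3D convex hull
#'
#' Lifts the contour points of one cell, collected across z-slices, to
#' physical coordinates (`x = (col-1) dx`, `y = (row-1) dy`,
#' `z = (slice-1) dz`) and takes their 3D convex hull as the cell's
#' volumetric model.
#'
#' @param contours list of `cell_contour` objects (see [segment_slice()])
#'   belonging to one cell, each with its `slice` index set; at least 2
#'   distinct slices.
#' @param voxel_size `c(dz, dy, dx)` in um.
#' @param cell_id identifier carried into the result.
#' @return An object of class `cell_reconstruction`: list with `cell_id`,
#'   `hull` (a [convex_hull_3d()] in um, columns x, y, z), `volume_um3`,
#'   `slice_range`.
#' @export
reconstruct_cell <- function(contours, voxel_size, cell_id = 1L) {
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  slices <- vapply(contours, function(ct) as.integer(ct$slice), integer(1L))
  if (anyNA(slices)) stop("every contour needs its 'slice' index set")
  if (length(unique(slices)) < 2L)
    stop("insufficient z-extent: contours span fewer than 2 slices")
  pts <- do.call(rbind, lapply(contours, function(ct) {
    b <- ct$boundary
    cbind(x = (b[, 2L] - 1) * voxel_size[3L],
          y = (b[, 1L] - 1) * voxel_size[2L],
          z = (ct$slice - 1) * voxel_size[1L])
  }))
  hull <- convex_hull_3d(pts)
  structure(list(cell_id = cell_id, hull = hull, volume_um3 = hull$volume,
                 slice_range = range(slices)),
            class = "cell_reconstruction")
}

#' @export
print.cell_reconstruction <- function(x, ...) {
  cat(sprintf("cell_reconstruction %s: volume %.4g um^3, slices %d-%d, %d hull vertices\n",
              x$cell_id, x$volume_um3, x$slice_range[1L], x$slice_range[2L],
              nrow(x$hull$vertices)))
  invisible(x)
}

#' Percent of a reconstructed cell's volume below the membrane
#'
#' The invasion readout: the exact fraction of the cell's convex-hull volume
#' with z below the upper membrane layer, computed by tetrahedral
#' decomposition of the hull and analytic clipping of each tetrahedron
#' against the half-space (see [hull_volume_below()]), expressed in percent.
#'
#' @param reconstruction a [reconstruct_cell()] result.
#' @param plane a [locate_membrane()] result, or a plain z position in um.
#' @return An object of class `invasion_result`: list with `cell_id`,
#'   `percent_invasion` (0-100), `volume_um3`, `membrane_z_um`.
#' @export
percent_invasion <- function(reconstruction, plane) {
  stopifnot(inherits(reconstruction, "cell_reconstruction"))
  z0 <- if (inherits(plane, "membrane_plane")) plane$z_um else as.numeric(plane)
  below <- hull_volume_below(reconstruction$hull, z0)
  structure(list(cell_id = reconstruction$cell_id,
                 percent_invasion = 100 * below / reconstruction$volume_um3,
                 volume_um3 = reconstruction$volume_um3,
                 membrane_z_um = z0),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("cell %s: %.1f%% of %.4g um^3 below the membrane (z = %.3g um)\n",
              x$cell_id, x$percent_invasion, x$volume_um3, x$membrane_z_um))
  invisible(x)
}

#' Run the full volumetric invasion pipeline on a two-channel stack
#'
#' End-to-end quantification of basement-membrane invasion from a confocal
#' z-stack: (1) locate the upper membrane layer in the membrane channel;
#' (2) segment the cell channel slice by slice ([segment_slice()]); (3) link
#' slice regions into cells by 3D connected components (overlap between
#' adjacent slices); (4) reduce every contour to its Teh-Chin dominant points
#' ([approximate_contour()]) — or to a fitted ellipse outline with
#' `hull_source = "ellipse"`; (5) reconstruct each cell as a 3D convex hull
#' in physical units ([reconstruct_cell()]); (6) compute percent volume below
#' the membrane ([percent_invasion()]). Regression ellipses are fitted to
#' every contour for QC regardless of `hull_source`.
#'
#' Cells spanning fewer than 2 slices are skipped (no 3D extent); cells whose
#' contours touch the lateral image border are skipped by default since their
#' volume would be truncated.
#'
#' @param stack an [image_stack()] with a cell and a membrane channel.
#' @param cell_channel,membrane_channel channel names.
#' @param smoothing_sigma,threshold,min_area_px,closing_px segmentation
#'   parameters, see [segment_slice()]. `threshold = "otsu"` here computes a
#'   single global Otsu threshold over the whole 3D cell channel (a per-slice
#'   threshold would hallucinate structure in slices that contain no cell).
#' @param hull_source `"contour"` (hull of dominant contour points, default)
#'   or `"ellipse"` (hull of fitted ellipse outlines).
#' @param exclude_border skip cells touching the lateral image border
#'   (default `TRUE`).
#' @param membrane_snr detection threshold for [locate_membrane()].
#' @return data.frame of class `invasion_results` with columns `cell_id`,
#'   `volume_um3`, `membrane_z_um`, `percent_invasion`; attributes
#'   `reconstructions` (list of [reconstruct_cell()] objects, e.g. for
#'   [write_mesh_obj()]), `skipped` (data.frame of skipped cells and
#'   reasons) and `membrane` (the [locate_membrane()] result).
#' @export
run_qpi <- function(stack, cell_channel = "cell",
                    membrane_channel = "membrane",
                    smoothing_sigma = 1, threshold = "otsu",
                    min_area_px = 50, closing_px = 3,
                    hull_source = c("contour", "ellipse"),
                    exclude_border = TRUE, membrane_snr = 3) {
  stopifnot(inherits(stack, "image_stack"))
  hull_source <- match.arg(hull_source)
  for (ch in c(cell_channel, membrane_channel))
    if (!ch %in% names(stack$channels))
      stop("no channel named '", ch, "' in the stack")
  membrane <- locate_membrane(stack, membrane_channel, snr = membrane_snr)
  cellch <- stack$channels[[cell_channel]]
  nz <- dim(cellch)[3L]
  if (identical(threshold, "otsu")) {
    rng <- range(cellch)
    if (diff(rng) == 0)
      threshold <- Inf                      # blank channel: nothing to find
    else {
      flat <- matrix((as.vector(cellch) - rng[1L]) / diff(rng), ncol = 1L)
      threshold <- rng[1L] +
        EBImage::otsu(flat, range = c(0, 1)) * diff(rng)
    }
  }
  segs <- lapply(seq_len(nz), function(iz) {
    s <- .segment_core(cellch[, , iz], smoothing_sigma, threshold,
                       min_area_px, closing_px)
    s$contours <- lapply(s$contours, function(ct) { ct$slice <- iz; ct })
    s
  })

  # 3D linking: union-find over (slice, label) nodes joined by voxel overlap
  parent <- integer(0)
  key <- function(iz, lab) paste0(iz, ":", lab)
  ids <- new.env(parent = emptyenv())
  getid <- function(k) {
    if (is.null(ids[[k]])) {
      parent[length(parent) + 1L] <<- length(parent) + 1L
      ids[[k]] <- length(parent)
    }
    ids[[k]]
  }
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (iz in seq_len(nz)) {
    for (ct in segs[[iz]]$contours) getid(key(iz, ct$label))
    if (iz == 1L) next
    l1 <- segs[[iz - 1L]]$labels; l2 <- segs[[iz]]$labels
    ov <- l1 > 0L & l2 > 0L
    if (!any(ov)) next
    pairs <- unique(cbind(l1[ov], l2[ov]))
    for (r in seq_len(nrow(pairs)))
      union(getid(key(iz - 1L, pairs[r, 1L])), getid(key(iz, pairs[r, 2L])))
  }

  groups <- list()
  for (iz in seq_len(nz)) for (ct in segs[[iz]]$contours) {
    root <- as.character(find(getid(key(iz, ct$label))))
    groups[[root]] <- c(groups[[root]], list(ct))
  }

  d <- dim(stack)
  res <- list(); recons <- list(); skipped <- list()
  cid <- 0L
  for (g in groups) {
    cid <- cid + 1L
    slices <- vapply(g, function(ct) ct$slice, integer(1L))
    if (length(unique(slices)) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(cell_id = cid, reason = "insufficient z-extent")
      next
    }
    if (exclude_border) {
      onb <- any(vapply(g, function(ct)
        any(ct$boundary[, 1L] <= 1L | ct$boundary[, 1L] >= d[1L] |
            ct$boundary[, 2L] <= 1L | ct$boundary[, 2L] >= d[2L]),
        logical(1L)))
      if (onb) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(cell_id = cid, reason = "touches image border")
        next
      }
    }
    g2 <- lapply(g, function(ct) {
      dp <- approximate_contour(ct$boundary)
      ct$dominant <- dp
      ct$ellipse <- if (nrow(ct$boundary) >= 5L)
        fit_ellipse(ct$boundary) else list(degenerate = TRUE)
      ct$boundary <- if (hull_source == "ellipse" &&
                         !isTRUE(ct$ellipse$degenerate))
        ellipse_points(ct$ellipse)
      else ct$boundary[dp, , drop = FALSE]
      ct
    })
    rec <- tryCatch(reconstruct_cell(g2, stack$voxel_size, cell_id = cid),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(cell_id = cid, reason = conditionMessage(rec))
      next
    }
    inv <- percent_invasion(rec, membrane)
    recons[[length(recons) + 1L]] <- rec
    res[[length(res) + 1L]] <-
      data.frame(cell_id = cid, volume_um3 = rec$volume_um3,
                 membrane_z_um = membrane$z_um,
                 percent_invasion = inv$percent_invasion)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cell_id = integer(), volume_um3 = numeric(),
               membrane_z_um = numeric(), percent_invasion = numeric())
  attr(out, "reconstructions") <- recons
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cell_id = integer(), reason = character())
  attr(out, "membrane") <- membrane
  class(out) <- c("invasion_results", "data.frame")
  out
}

#' Export a cell reconstruction as a Wavefront OBJ mesh
#'
#' @param reconstruction a [reconstruct_cell()] result (or a
#'   [convex_hull_3d()]).
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(reconstruction, path) {
  hull <- if (inherits(reconstruction, "cell_reconstruction"))
    reconstruction$hull else reconstruction
  stopifnot(inherits(hull, "convex_hull_3d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", hull$vertices[, 1L],
                     hull$vertices[, 2L], hull$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", hull$faces[, 1L], hull$faces[, 2L],
                     hull$faces[, 3L]), con)
  invisible(path)
}

#' Cumulative invaded-cell count per mesentery per ROI
#'
#' Normalisation used for counting fully-transmigrated cells over a
#' multi-day invasion assay: each day's mean cell count per region of
#' interest is divided by the number of mesenteries in the well, and both the
#' daily means and their standard errors are accumulated as running sums
#' across days.
#'
#' @param daily_counts either a list with one numeric vector of per-ROI
#'   counts per day, or a numeric vector of per-day mean counts (then
#'   `daily_se` supplies the per-day standard errors, default 0).
#' @param mesenteries number of mesenteries per well: scalar or one value per
#'   day; must be >= 1.
#' @param daily_se per-day standard errors when `daily_counts` is a vector of
#'   means; ignored otherwise.
#' @return data.frame of class `cumulative_count`: `day`, `mean_per_roi`
#'   (per mesentery), `se`, `cumulative`, `cumulative_se`.
#' @examples
#' cumulative_invaded_count(c(2, 3), mesenteries = 1, daily_se = c(0.5, 0.5))
#' @export
cumulative_invaded_count <- function(daily_counts, mesenteries,
                                     daily_se = NULL) {
  if (is.list(daily_counts)) {
    means <- vapply(daily_counts, mean, numeric(1L))
    ses <- vapply(daily_counts, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0, numeric(1L))
  } else {
    means <- as.numeric(daily_counts)
    ses <- if (is.null(daily_se)) rep(0, length(means)) else
      rep_len(as.numeric(daily_se), length(means))
  }
  ndays <- length(means)
  mes <- rep_len(as.numeric(mesenteries), ndays)
  if (any(mes < 1)) stop("mesentery counts must be >= 1")
  if (length(ses) != ndays) stop("daily_se length must match daily_counts")
  m <- means / mes
  s <- ses / mes
  structure(data.frame(day = seq_len(ndays), mean_per_roi = m, se = s,
                       cumulative = cumsum(m), cumulative_se = cumsum(s)),
            class = c("cumulative_count", "data.frame"))
}
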