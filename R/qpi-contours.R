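#' Segment one z-slice into cell contours
#'
#' The filter chain that turns a raw fluorescence slice into ordered cell
#' boundaries: Gaussian smoothing, Otsu threshold (or a fixed threshold),
#' morphological closing, connected components, and boundary tracing. Small
#' components (below `min_area_px`) are discarded. Each detected region
#' yields one closed contour of ordered boundary pixels.
#'
#' @param image 2D intensity matrix `[y, x]`.
#' @param smoothing_sigma Gaussian smoothing sigma in px (0 disables).
#' @param threshold `"otsu"` (default) or a numeric intensity cutoff.
#' @param min_area_px minimum region area in px.
#' @param closing_px diameter of the morphological closing brush, px
#'   (0 disables).
#' @param min_separability with Otsu thresholding, the minimum between-class
#'   variance fraction (Otsu's separability) required to accept that the
#'   slice contains foreground at all; a unimodal noise-only image scores
#'   about 0.63 and yields an empty result, a slice with a real object
#'   typically scores above 0.9. Ignored for a numeric `threshold`.
#' @return list of `cell_contour` objects (possibly empty): each has
#'   `boundary` (matrix `[point, c(y, x)]`, 1-based pixel coordinates,
#'   ordered around the region), `area_px`, `label` (component id within the
#'   slice) and `slice` (`NA` here; filled by the pipeline).
#' @export
segment_slice <- function(image, smoothing_sigma = 1, threshold = "otsu",
                          min_area_px = 50, closing_px = 3,
                          min_separability = 0.75) {
  .segment_core(image, smoothing_sigma, threshold, min_area_px,
                closing_px, min_separability)$contours
}

# full segmentation result: pruned label image + ordered contours
.segment_core <- function(image, smoothing_sigma = 1, threshold = "otsu",
                          min_area_px = 50, closing_px = 3,
                          min_separability = 0.75) {
  stopifnot(is.matrix(image))
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                contours = list())
  img <- image
  if (smoothing_sigma > 0) img <- EBImage::gblur(img, smoothing_sigma)
  rng <- range(img)
  if (diff(rng) == 0) return(empty)
  if (identical(threshold, "otsu")) {
    norm <- (img - rng[1L]) / diff(rng)
    thr <- rng[1L] + EBImage::otsu(norm, range = c(0, 1)) * diff(rng)
    if (.otsu_separability(img, thr) < min_separability) return(empty)
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- img > thr
  if (!any(mask)) return(empty)
  mask <- EBImage::Image(mask * 1)
  if (closing_px > 0)
    mask <- EBImage::closing(mask,
                             EBImage::makeBrush(.odd(closing_px), "disc"))
  lab <- EBImage::bwlabel(mask)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_area_px])
  if (length(keep) == 0L) return(empty)
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (id in keep) {
    b <- oc[[id]]
    if (is.null(b) || nrow(b) < 3L) next
    b <- b + 1L                             # EBImage contours are 0-based
    b <- .ccw(b)
    out[[length(out) + 1L]] <- structure(
      list(boundary = unname(b), area_px = as.integer(areas[as.character(id)]),
           label = id, slice = NA_integer_),
      class = "cell_contour")
  }
  labels <- array(as.integer(as.array(lab)), dim = dim(image))
  kept <- vapply(out, function(ct) ct$label, integer(1L))
  labels[!labels %in% kept] <- 0L
  list(labels = labels, contours = out)
}

.odd <- function(n) { n <- max(1L, round(n)); if (n %% 2L == 0L) n + 1L else n }

# Otsu's separability: between-class variance / total variance at the given
# threshold; ~0.63 for unimodal Gaussian noise, -> 1 for well-separated modes
.otsu_separability <- function(img, thr) {
  fg <- img > thr
  w1 <- mean(fg)
  if (w1 == 0 || w1 == 1) return(0)
  tot <- stats::var(as.vector(img))
  if (tot == 0) return(0)
  (1 - w1) * w1 * (mean(img[fg]) - mean(img[!fg]))^2 / tot
}

# enforce counter-clockwise orientation (shoelace in (y, x) pixel coords)
.ccw <- function(b) {
  y <- b[, 1L]; x <- b[, 2L]
  a2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
  if (a2 < 0) b[rev(seq_len(nrow(b))), , drop = FALSE] else b
}

#' Dominant points of a closed digital contour (Teh-Chin)
#'
#' Adaptive dominant-point detection on a closed chain of boundary pixels,
#' following Teh and Chin's region-of-support approach: for every point the
#' support arm length k grows while the chord through `p[i-k], p[i+k]`
#' lengthens and the perpendicular-distance-to-chord ratio keeps shrinking;
#' the point's significance is its k-cosine (angle between the two support
#' arms) and non-maxima suppression over each point's region of support
#' leaves the dominant points. Collinear runs produce no interior dominant
#' points; corners of a polygon are retained exactly.
#'
#' @param boundary matrix `[point, c(y, x)]` of an ordered *closed* chain
#'   (first point adjacent to last); at least 3 points.
#' @return integer vector of indices into `boundary` (the dominant points,
#'   in chain order).
#' @export
approximate_contour <- function(boundary) {
  b <- as.matrix(boundary)
  n <- nrow(b)
  if (n < 3L) stop("need at least 3 boundary points")
  if (max(abs(b[n, ] - b[1L, ])) > 1.5 * max(abs(diff(b)), 1))
    stop("boundary chain is not closed")
  if (n <= 4L) return(seq_len(n))
  kmax <- max(1L, min(n %/% 2L - 1L, 50L))
  idx <- function(i) ((i - 1L) %% n) + 1L

  sup <- integer(n)                # region of support k_i
  meas <- numeric(n)               # significance: k-cosine in [-1, 1]
  for (i in seq_len(n)) {
    p <- b[i, ]
    lprev <- 0; rprev <- Inf; k_i <- 1L
    for (k in seq_len(kmax)) {
      a <- b[idx(i - k), ]; c2 <- b[idx(i + k), ]
      ch <- c2 - a
      l <- sqrt(sum(ch^2))
      d <- if (l == 0) 0 else
        abs(ch[2L] * (p[1L] - a[1L]) - ch[1L] * (p[2L] - a[2L])) / l
      r <- if (l == 0) Inf else d / l
      if (k > 1L && !(l > lprev && r <= rprev + 1e-12)) break
      k_i <- k; lprev <- l; rprev <- r
    }
    sup[i] <- k_i
    va <- b[idx(i - k_i), ] - p
    vc <- b[idx(i + k_i), ] - p
    meas[i] <- sum(va * vc) / sqrt(sum(va^2) * sum(vc^2))
  }
  curv <- meas                # k-cosine: +1 at sharp corners, -1 on straights

  # pass 1: keep points whose measure is maximal over their support window
  keep <- vapply(seq_len(n), function(i) {
    h <- max(1L, sup[i] %/% 2L)
    all(curv[i] >= curv[idx(i + seq(-h, h))] - 1e-12)
  }, logical(1L))
  # pass 2: drop survivors with support 1 that sit next to a stronger one
  for (i in which(keep & sup == 1L)) {
    nb <- idx(c(i - 1L, i + 1L))
    if (any(keep[nb] & curv[nb] > curv[i])) keep[i] <- FALSE
  }
  # pass 3: collapse runs of adjacent survivors to their best point
  surv <- which(keep)
  if (length(surv) > 1L) {
    gap <- c(diff(surv), surv[1L] + n - surv[length(surv)])
    run_id <- cumsum(c(TRUE, diff(surv) > 1L))
    if (gap[length(gap)] == 1L && length(unique(run_id)) > 1L)
      run_id[run_id == max(run_id)] <- run_id[1L]   # wrap-around run
    surv <- vapply(split(surv, run_id), function(g) {
      g[which.max(curv[g] + sup[g] / (10 * n))]     # support breaks ties
    }, integer(1L))
    surv <- sort(unname(surv))
  }
  # drop flat points (arms nearly antiparallel) unless that empties the set
  sharp <- surv[curv[surv] > -0.999]
  if (length(sharp) >= 3L) surv <- sharp
  surv
}

#' Least-squares ellipse fit (direct conic method)
#'
#' Fits an ellipse to 2D points by the numerically stable direct
#' least-squares conic fit (Halir & Flusser's partitioning of Fitzgibbon's
#' method), which constrains the conic to be an ellipse. Exact points on an
#' ellipse are recovered to numerical precision.
#'
#' @param points matrix `[point, c(y, x)]` (or `(x, y)`; the fit is symmetric
#'   in the two columns, reported in the input's column order as `center =
#'   (col1, col2)`).
#' @return list with `center` (length 2), `semi_axes` (major, minor),
#'   `angle_rad` (orientation of the major axis relative to the first
#'   coordinate axis) and `degenerate = FALSE`; or `list(degenerate = TRUE)`
#'   for collinear/degenerate input.
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5L) stop("ellipse fitting needs at least 5 points")
  u <- pts[, 1L]; v <- pts[, 2L]
  mu <- mean(u); mv <- mean(v)
  u <- u - mu; v <- v - mv
  sv <- svd(cbind(u, v))
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    return(list(degenerate = TRUE))
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T2)) return(list(degenerate = TRUE))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  eg <- eigen(M)
  cond <- 4 * Re(eg$vectors[1L, ]) * Re(eg$vectors[3L, ]) -
    Re(eg$vectors[2L, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(list(degenerate = TRUE))
  a1 <- Re(eg$vectors[, ok[1L]])
  coefs <- c(a1, as.vector(T2 %*% a1))      # A B C D E F in centred coords
  A <- coefs[1L]; B <- coefs[2L]; C <- coefs[3L]
  D <- coefs[4L]; E <- coefs[5L]; F0 <- coefs[6L]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(list(degenerate = TRUE))
  cu <- (2 * C * D - B * E) / den
  cv <- (2 * A * E - B * D) / den
  Fc <- F0 + A * cu^2 + B * cu * cv + C * cv^2 + D * cu + E * cv
  m <- matrix(c(A, B / 2, B / 2, C), 2L)
  ev <- eigen(m, symmetric = TRUE)
  ax2 <- -Fc / ev$values
  if (any(ax2 <= 0)) return(list(degenerate = TRUE))
  axes <- sqrt(ax2)
  ord <- order(axes, decreasing = TRUE)
  major_vec <- ev$vectors[, ord[1L]]
  list(center = c(cu + mu, cv + mv),
       semi_axes = axes[ord],
       angle_rad = atan2(major_vec[2L], major_vec[1L]),
       degenerate = FALSE)
}

#' Sample points on a fitted ellipse outline
#'
#' @param ellipse a non-degenerate [fit_ellipse()] result.
#' @param n number of points.
#' @return matrix `[n, 2]` in the same coordinate order as the fit input.
#' @export
ellipse_points <- function(ellipse, n = 36L) {
  stopifnot(!isTRUE(ellipse$degenerate))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  a <- ellipse$semi_axes[1L]; b2 <- ellipse$semi_axes[2L]
  ca <- cos(ellipse$angle_rad); sa <- sin(ellipse$angle_rad)
  u <- a * cos(th); v <- b2 * sin(th)
  cbind(ellipse$center[1L] + u * ca - v * sa,
        ellipse$center[2L] + u * sa + v * ca)
}
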