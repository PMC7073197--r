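#' 3D convex hull of a point cloud
#'
#' Computes the convex hull of a set of 3D points with an incremental
#' beneath-beyond algorithm, returning the hull vertices, outward-oriented
#' triangular facets and the enclosed volume. This is the geometric engine
#' behind cell reconstruction: the hull of all contour points of one cell,
#' lifted to physical coordinates, is the cell's volumetric model.
#'
#' @param points numeric matrix with 3 columns (x, y, z), one point per row.
#' @param tol relative tolerance used to decide whether a point lies on a
#'   facet plane; scaled by the extent of the cloud.
#'
#' @return A list of class `convex_hull_3d` with components:
#'   \describe{
#'     \item{vertices}{matrix of hull vertex coordinates (subset of input).}
#'     \item{faces}{integer matrix, 3 columns, rows indexing `vertices`;
#'       vertices of every facet are ordered so the facet normal points
#'       outward.}
#'     \item{volume}{enclosed volume (cube of the input length unit).}
#'     \item{area}{total surface area.}
#'     \item{centroid}{an interior point (mean of hull vertices).}
#'   }
#' @examples
#' pts <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' h <- convex_hull_3d(pts)
#' h$volume  # 1, the unit cube
#' @export
convex_hull_3d <- function(points, tol = 1e-10) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("'points' contains NA")
  pts <- unique(points)
  if (nrow(pts) < 4L)
    stop("need at least 4 distinct points for a 3D hull")

  scale <- max(apply(pts, 2L, function(v) diff(range(v))), .Machine$double.eps)
  eps <- tol * scale

  init <- .hull_initial_tetra(pts, eps)
  if (is.null(init))
    stop("points are degenerate (coplanar or collinear); no 3D hull exists")

  # the centroid of the starting tetrahedron stays interior as the hull grows
  interior <- colMeans(pts[unique(unlist(init)), , drop = FALSE])

  cap <- 8L * length(init)
  fm <- matrix(0L, cap, 3L)      # faces, rows index pts
  nm <- matrix(0, cap, 3L)       # outward normals
  dv <- numeric(cap)             # plane offsets (n . x = d)
  alive <- logical(cap)
  nf <- 0L
  add_face <- function(tri) {
    tri <- .orient_face(tri, pts, interior)
    if (nf == cap) {
      cap <<- cap * 2L
      fm2 <- matrix(0L, cap, 3L); fm2[seq_len(nf), ] <- fm; fm <<- fm2
      nm2 <- matrix(0, cap, 3L); nm2[seq_len(nf), ] <- nm; nm <<- nm2
      length(dv) <<- cap; length(alive) <<- cap
    }
    nf <<- nf + 1L
    fm[nf, ] <<- tri
    a <- pts[tri[1L], ]
    n <- .cross3(pts[tri[2L], ] - a, pts[tri[3L], ] - a)
    nm[nf, ] <<- n
    dv[nf] <<- sum(n * a)
    alive[nf] <<- TRUE
  }
  for (tri in init) add_face(tri)

  remaining <- setdiff(seq_len(nrow(pts)), unlist(init))
  for (p in remaining) {
    live <- which(alive[seq_len(nf)])
    excess <- as.vector(nm[live, , drop = FALSE] %*% pts[p, ]) - dv[live]
    # visibility scaled by facet normal length so eps is a true distance
    vis <- live[excess > eps * sqrt(rowSums(nm[live, , drop = FALSE]^2))]
    if (!length(vis)) next
    edges <- rbind(fm[vis, c(1L, 2L), drop = FALSE],
                   fm[vis, c(2L, 3L), drop = FALSE],
                   fm[vis, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[vis] <- FALSE
    for (i in seq_len(nrow(horizon))) add_face(c(horizon[i, ], p))
  }

  live <- which(alive[seq_len(nf)])
  vid <- sort(unique(as.vector(fm[live, ])))
  remap <- integer(nrow(pts)); remap[vid] <- seq_along(vid)
  fmat <- matrix(remap[fm[live, ]], ncol = 3L)
  verts <- pts[vid, , drop = FALSE]
  centroid <- colMeans(verts)
  # re-orient every facet outward w.r.t. the centroid and accumulate volume
  vol <- 0; area <- 0
  for (i in seq_len(nrow(fmat))) {
    a <- verts[fmat[i, 1L], ]; b <- verts[fmat[i, 2L], ]; c3 <- verts[fmat[i, 3L], ]
    n <- .cross3(b - a, c3 - a)
    if (sum(n * (a - centroid)) < 0) {
      fmat[i, ] <- fmat[i, c(1L, 3L, 2L)]
      n <- -n
    }
    area <- area + sqrt(sum(n^2)) / 2
    vol <- vol + .tetra_signed_volume(centroid, verts[fmat[i, 1L], ],
                                      verts[fmat[i, 2L], ], verts[fmat[i, 3L], ])
  }
  structure(list(vertices = verts, faces = fmat, volume = vol,
                 area = area, centroid = centroid),
            class = "convex_hull_3d")
}

#' @export
print.convex_hull_3d <- function(x, ...) {
  cat("3D convex hull:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "facets\n")
  cat(sprintf("  volume %.6g, surface area %.6g\n", x$volume, x$area))
  invisible(x)
}

# initial non-degenerate tetrahedron from extreme points
.hull_initial_tetra <- function(pts, eps) {
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) return(NULL)
  a <- pts[i1, ]; b <- pts[i2, ]
  ab <- b - a
  d2 <- apply(pts, 1L, function(p) {
    v <- .cross3(ab, p - a); sum(v^2)
  })
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) <= eps * sqrt(sum(ab^2))) return(NULL)
  n <- .cross3(ab, pts[i3, ] - a)
  h <- abs(as.vector(pts %*% n) - sum(n * a)) / sqrt(sum(n^2))
  i4 <- which.max(h)
  if (h[i4] <= eps) return(NULL)
  ids <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[ids, , drop = FALSE])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  lapply(faces, .orient_face, pts = pts, interior = interior)
}

.orient_face <- function(tri, pts, interior) {
  a <- pts[tri[1L], ]; b <- pts[tri[2L], ]; c3 <- pts[tri[3L], ]
  n <- .cross3(b - a, c3 - a)
  if (sum(n * (a - interior)) < 0) tri[c(1L, 3L, 2L)] else tri
}

.face_plane <- function(tri, pts) {
  a <- pts[tri[1L], ]
  n <- .cross3(pts[tri[2L], ] - a, pts[tri[3L], ] - a)
  list(n = n, d = sum(n * a))
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.tetra_signed_volume <- function(a, b, c3, d) {
  u <- b - a; v <- c3 - a; w <- d - a
  sum(u * .cross3(v, w)) / 6
}

#' Volume of a convex hull below a horizontal plane
#'
#' Exact volume of the part of a convex polytope lying below `z = z0`,
#' computed by decomposing the hull into tetrahedra (hull centroid + each
#' triangular facet) and clipping every tetrahedron against the half-space
#' analytically. No sampling is involved; the result is exact up to
#' floating-point rounding.
#'
#' @param hull a `convex_hull_3d` object.
#' @param z0 plane height (same unit as the hull coordinates); the half-space
#'   is `z < z0`.
#' @return volume below the plane, in `[0, hull$volume]`.
#' @seealso [percent_invasion()] which expresses this as a percentage.
#' @export
hull_volume_below <- function(hull, z0) {
  stopifnot(inherits(hull, "convex_hull_3d"))
  v <- hull$vertices; f <- hull$faces; cen <- hull$centroid
  total <- 0
  for (i in seq_len(nrow(f))) {
    total <- total + .clip_tetra_below(rbind(cen,
                                             v[f[i, 1L], ],
                                             v[f[i, 2L], ],
                                             v[f[i, 3L], ]), z0)
  }
  min(max(total, 0), hull$volume)
}

# volume of the part of tetrahedron `tet` (4x3 matrix) with z < z0
.clip_tetra_below <- function(tet, z0) {
  d <- z0 - tet[, 3L]                      # positive = below the plane
  below <- d > 0
  nb <- sum(below)
  vol <- abs(.tetra_signed_volume(tet[1L, ], tet[2L, ], tet[3L, ], tet[4L, ]))
  if (nb == 0L) return(0)
  if (nb == 4L) return(vol)
  ix <- function(pa, pb) {               # plane intersection on edge pa->pb
    t <- d[pa] / (d[pa] - d[pb])
    tet[pa, ] + t * (tet[pb, ] - tet[pa, ])
  }
  if (nb == 1L) {
    p <- which(below); q <- which(!below)
    # similar tetrahedron cut off at the single below-vertex
    return(vol * d[p]^3 / ((d[p] - d[q[1L]]) * (d[p] - d[q[2L]]) * (d[p] - d[q[3L]])))
  }
  if (nb == 3L) {
    q <- which(!below); p <- which(below)
    above <- vol * d[q]^3 / ((d[q] - d[p[1L]]) * (d[q] - d[p[2L]]) * (d[q] - d[p[3L]]))
    return(vol - abs(above))
  }
  # nb == 2: clipped solid is a triangular prismatoid; split into 3 tetrahedra
  p <- which(below); q <- which(!below)
  A1 <- tet[p[1L], ]; A2 <- tet[p[2L], ]
  B1 <- ix(p[1L], q[1L]); C1 <- ix(p[1L], q[2L])
  B2 <- ix(p[2L], q[1L]); C2 <- ix(p[2L], q[2L])
  abs(.tetra_signed_volume(A1, B1, C1, A2)) +
    abs(.tetra_signed_volume(B1, C1, A2, B2)) +
    abs(.tetra_signed_volume(C1, A2, B2, C2))
}

# Monte-Carlo point-in-hull oracle used by the test-suite; exported because it
# is also the cross-check the acceptance checks rely on.

#' Monte-Carlo estimate of the hull volume fraction below a plane
#'
#' Independent sampling-based oracle for [hull_volume_below()]: samples points
#' uniformly in the hull's bounding box, keeps those inside the hull
#' (half-space test against every facet) and reports the fraction of interior
#' samples with `z < z0`. Used to cross-validate the exact tetrahedral
#' clipping; deliberately shares no code with it.
#'
#' @param hull a `convex_hull_3d` object.
#' @param z0 plane height.
#' @param n number of bounding-box samples.
#' @return list with `fraction_below` (percent) and `volume` (MC estimate of
#'   the hull volume).
#' @export
mc_fraction_below <- function(hull, z0, n = 1e6) {
  v <- hull$vertices
  lo <- apply(v, 2L, min); hi <- apply(v, 2L, max)
  x <- cbind(stats::runif(n, lo[1L], hi[1L]),
             stats::runif(n, lo[2L], hi[2L]),
             stats::runif(n, lo[3L], hi[3L]))
  inside <- rep(TRUE, n)
  for (i in seq_len(nrow(hull$faces))) {
    f <- hull$faces[i, ]
    a <- v[f[1L], ]
    nrm <- .cross3(v[f[2L], ] - a, v[f[3L], ] - a)
    inside <- inside & (x %*% nrm - sum(nrm * a) <= 0)
    if (!any(inside)) break
  }
  nin <- sum(inside)
  if (nin == 0L) stop("no sample fell inside the hull; increase n")
  frac <- 100 * sum(inside & x[, 3L] < z0) / nin
  boxvol <- prod(hi - lo)
  list(fraction_below = frac, volume = boxvol * nin / n)
}
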