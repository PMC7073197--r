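#' Multichannel 3D image stack
#'
#' Container for a multichannel confocal z-stack with physical voxel sizes.
#' Each channel is a 3D array indexed `[y, x, z]` (1-based); the physical
#' position of a voxel centre is `(index - 1) * voxel size` along each axis,
#' so slice 1 sits at z = 0 um. Slice index increases with physical z and
#' z = 0 is the substrate side *below* the basement membrane: cells seeded on
#' top of the membrane invade toward decreasing z.
#'
#' @param channels named list of 3D numeric arrays, all the same dimension
#'   `c(ny, nx, nz)`, nonnegative intensities.
#' @param voxel_size numeric length 3, `c(dz, dy, dx)` in micrometres.
#' @return An object of class `image_stack`.
#' @examples
#' a <- array(0, c(8, 8, 4))
#' s <- image_stack(list(actin = a, laminin = a), voxel_size = c(0.2, 0.1, 0.1))
#' dim(s)
#' @export
image_stack <- function(channels, voxel_size = c(0.2, 0.1, 0.1)) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of 3D arrays")
  nms <- names(channels)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    stop("channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a 3D array [y, x, z]")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (dz, dy, dx) in um")
  if (any(dims[[1L]] < 1L)) stop("all dimensions must be >= 1")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d px, %d z-slices\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], d[3L]))
  cat(sprintf("  voxel size (dz, dy, dx): %.3g x %.3g x %.3g um; z-range 0-%.3g um\n",
              x$voxel_size[1L], x$voxel_size[2L], x$voxel_size[3L],
              (d[3L] - 1L) * x$voxel_size[1L]))
  invisible(x)
}

# z positions (um) of all slices of a stack
.slice_z <- function(stack) {
  (seq_len(dim(stack)[3L]) - 1L) * stack$voxel_size[1L]
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multipage TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z-slices of channel 1, then channel 2,
#' ...). Physical metadata (voxel sizes, channel names, dimensions and the
#' intensity scale used to map data into TIFF's unit range) goes to a JSON
#' sidecar at `<path>.json`. Integer data in `[0, 65535]` are stored as
#' 16-bit pages and round-trip exactly; anything else is stored as 32-bit
#' fixed-point pages divided by a power-of-two scale, which round-trips with
#' a worst-case error of `scale / 2^32` (far below fluorescence noise).
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param force overwrite an existing file? Default `FALSE` (refused with an
#'   error).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, force = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (file.exists(path) && !force)
    stop("'", path, "' exists; use force = TRUE to overwrite")
  vals <- unlist(lapply(stack$channels, range))
  if (any(!is.finite(vals))) stop("stack contains non-finite values")
  if (min(vals) < 0) stop("stack intensities must be nonnegative")
  integral <- all(vapply(stack$channels,
                         function(a) all(a == round(a)), logical(1L)))
  if (integral && max(vals) <= 65535) {
    bits <- 16L
    scale <- 65535
  } else {
    bits <- 32L
    scale <- 2^max(0, ceiling(log2(max(vals, 1))))
  }
  pages <- list()
  for (ch in stack$channels)
    for (iz in seq_len(dim(ch)[3L]))
      pages[[length(pages) + 1L]] <- ch[, , iz] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(voxel_size_um = stack$voxel_size,
               channels = names(stack$channels),
               dim = dim(stack), bits = bits, intensity_scale = scale)
  jsonlite::write_json(meta, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel stack from a multipage TIFF
#'
#' Reads TIFFs written by [write_stack()] (using the JSON sidecar for layout
#' and physical metadata), or plain multipage TIFFs from other sources, in
#' which case the channel count and voxel sizes must be supplied.
#'
#' @param path TIFF path.
#' @param voxel_size optional `c(dz, dy, dx)` in um, overriding (or supplying,
#'   when there is no sidecar) the voxel sizes.
#' @param channels optional character vector of channel names; with no
#'   sidecar, its length defines how many equal blocks the pages split into
#'   (default: one channel).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pagedim <- lapply(pages, dim)
  if (length(unique(pagedim)) != 1L)
    stop("ragged TIFF: pages differ in size")
  sidecar <- .sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
    if (is.null(channels)) channels <- meta$channels
    scale <- meta$intensity_scale
  } else {
    if (is.null(voxel_size))
      stop("no JSON sidecar next to '", path,
           "'; pass voxel_size = c(dz, dy, dx) in um")
    if (is.null(channels)) channels <- "channel1"
    scale <- 1
  }
  nc <- length(channels)
  if (length(pages) %% nc != 0L)
    stop("page count ", length(pages), " is not divisible by ",
         nc, " channels")
  nz <- length(pages) %/% nc
  arrs <- vector("list", nc)
  for (ci in seq_len(nc)) {
    block <- pages[(ci - 1L) * nz + seq_len(nz)]
    a <- array(unlist(block), c(dim(block[[1L]]), nz)) * scale
    if (scale == 65535) a <- round(a)       # 16-bit integer pages are exact
    arrs[[ci]] <- a
  }
  names(arrs) <- channels
  image_stack(arrs, voxel_size = voxel_size)
}

#' Region of interest on an image
#'
#' A labelled set of pixel (or voxel) coordinates. 2D regions are `[y, x]`
#' index matrices, 3D regions `[y, x, z]`; indices are 1-based.
#'
#' @param coords integer matrix with 2 or 3 columns of pixel indices.
#' @param label short name for the region.
#' @return An object of class `image_roi`.
#' @export
image_roi <- function(coords, label = "roi") {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("ROI '", label, "' is empty")
  if (!ncol(coords) %in% c(2L, 3L))
    stop("ROI coordinates must have 2 (y, x) or 3 (y, x, z) columns")
  storage.mode(coords) <- "integer"
  if (any(coords < 1L)) stop("ROI indices must be >= 1")
  structure(list(coords = coords, label = label), class = "image_roi")
}

#' Background-subtracted mean intensity of a region
#'
#' The standard immunofluorescence readout: the mean marker intensity over a
#' selected region minus the mean over a background region drawn on the same
#' image. No trimming or robust estimation is applied, and a negative result
#' (marker dimmer than background) is returned as-is. The statistic is by
#' construction invariant under adding a constant offset to the whole image.
#'
#' @param image 2D matrix `[y, x]` or 3D array `[y, x, z]` of intensities.
#' @param marker_region an [image_roi()] over the marker signal.
#' @param background_region an [image_roi()] over a signal-free area.
#' @return single number: `mean(marker) - mean(background)`, in the image's
#'   intensity units.
#' @examples
#' img <- matrix(10, 32, 32)
#' img[5:10, 5:10] <- 110
#' m <- image_roi(as.matrix(expand.grid(y = 5:10, x = 5:10)), "marker")
#' b <- image_roi(as.matrix(expand.grid(y = 20:30, x = 20:30)), "bg")
#' quantify_intensity(img, m, b)  # 100
#' @export
quantify_intensity <- function(image, marker_region, background_region) {
  stopifnot(inherits(marker_region, "image_roi"),
            inherits(background_region, "image_roi"))
  m <- .roi_values(image, marker_region)
  b <- .roi_values(image, background_region)
  km <- apply(marker_region$coords, 1L, paste, collapse = ",")
  kb <- apply(background_region$coords, 1L, paste, collapse = ",")
  if (any(km %in% kb))
    warning("marker and background regions overlap")
  mean(m) - mean(b)
}

.roi_values <- function(image, roi) {
  d <- dim(image)
  if (ncol(roi$coords) != length(d))
    stop("ROI '", roi$label, "' dimensionality (", ncol(roi$coords),
         ") does not match the image (", length(d), ")")
  if (any(sweep(roi$coords, 2L, d, ">") ))
    stop("ROI '", roi$label, "' extends outside the image")
  image[roi$coords]
}
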