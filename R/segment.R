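#' Color deconvolution into H&E stain densities
#'
#' Converts an RGB image to optical densities by the Beer-Lambert
#' log-transform and projects them onto a fixed H&E stain basis (the
#' standard published hematoxylin/eosin vectors plus their orthogonal
#' residual), yielding one stain-density raster per stain.
#'
#' @param image an `nm_spot_image` or height x width x 3 array in `[0, 1]`.
#' @param stain_matrix 3 x 3 matrix of unit stain vectors (rows =
#'   hematoxylin, eosin, residual; columns = R, G, B). Defaults to the
#'   standard H&E basis.
#' @param io background (white) intensity on the image scale.
#' @return list with numeric matrices `hematoxylin`, `eosin`, `residual`
#'   (optical-density units, clamped at 0).
#' @export
color_deconvolve <- function(image, stain_matrix = he_stain_matrix(),
                             io = 1) {
  px <- if (inherits(image, "nm_spot_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  if (all(px == 0)) stop("all-zero image: optical density undefined")
  stopifnot(nrow(stain_matrix) == 3, ncol(stain_matrix) == 3)
  eps <- 1 / 255
  od <- -log10(pmax(px, eps) / io)            # H x W x 3
  h <- dim(px)[1]; w <- dim(px)[2]
  odm <- matrix(od, h * w, 3)
  # od = density %*% stain_matrix (rows = stains), so invert on the right
  dens <- odm %*% solve(stain_matrix)
  dens[dens < 0] <- 0
  list(hematoxylin = matrix(dens[, 1], h, w),
       eosin = matrix(dens[, 2], h, w),
       residual = matrix(dens[, 3], h, w))
}

#' Watershed-based nuclear segmentation
#'
#' Segments nuclei from a hematoxylin density raster: Otsu threshold,
#' distance transform of the foreground, marker-controlled watershed on the
#' smoothed distance map, then area filtering. Deterministic given
#' identical inputs.
#'
#' @param hema hematoxylin density matrix from [color_deconvolve()].
#' @param min_area_px,max_area_px retained object area bounds (defaults 30
#'   and 5000 px^2 at 0.25 um/px).
#' @param smooth_sigma Gaussian sigma applied to the distance map before
#'   maxima detection/watershed.
#' @param tolerance watershed merge tolerance on the distance map (px).
#' @return object of class `nm_nuclear_mask`: list with `labels` (integer
#'   matrix, 0 background, k > 0 nucleus k, relabeled 1..n) and `n_nuclei`.
#'   An empty foreground yields `n_nuclei = 0` with a warning.
#' @export
segment_nuclei <- function(hema, min_area_px = 30, max_area_px = 5000,
                           smooth_sigma = 2, tolerance = 1) {
  stopifnot(is.matrix(hema), min_area_px >= 1, max_area_px > min_area_px)
  rng <- range(hema)
  if (rng[2] <= rng[1]) {
    warning("constant hematoxylin raster: no nuclei found")
    return(new_nuclear_mask(matrix(0L, nrow(hema), ncol(hema))))
  }
  norm <- (hema - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) {
    warning("empty foreground after Otsu threshold: no nuclei found")
    return(new_nuclear_mask(matrix(0L, nrow(hema), ncol(hema))))
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  dms <- EBImage::gblur(dm, sigma = smooth_sigma)
  dms[fg == 0] <- 0
  ws <- EBImage::watershed(dms, tolerance = tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)),
                   nrow(hema), ncol(hema))
  # area filter + sequential relabel
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= min_area_px & tab <= max_area_px)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- remap[labels[pos]]
  new_nuclear_mask(labels)
}

#' Nuclear mask container
#' @param labels integer label matrix (0 = background).
#' @return `nm_nuclear_mask` with fields `labels`, `n_nuclei`.
#' @export
new_nuclear_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  u <- sort(unique(labels[labels > 0]))
  structure(list(labels = labels, n_nuclei = length(u)),
            class = "nm_nuclear_mask")
}

get_mask_labels <- function(mask) {
  if (inherits(mask, "nm_nuclear_mask")) mask$labels else mask
}

# 8-connected boundary polygon of one labeled object, ordered. Uses the
# EBImage contour tracer; vertices are (x = col, y = row) pixel centers.
object_contour <- function(labels, k) {
  m <- matrix(0L, nrow(labels), ncol(labels))
  m[labels == k] <- 1L
  # EBImage images index as [x, y]; transpose so x = column
  oc <- EBImage::ocontour(EBImage::Image(t(m)))[[1]]
  # ocontour returns 0-based (x, y); shift to 1-based pixel centers
  cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
}

#' Extract per-nucleus records from a labeled mask
#'
#' One record per label, carrying the boundary polygon, centroid,
#' second-moment ellipse fit and per-channel interior intensities — the
#' quantities all downstream feature families consume. The orientation is
#' the major-axis angle of the moment ellipse in degrees, mapped to
#' `[0, 180)`, measured counterclockwise from the +x (column) axis with y
#' pointing up. Near-circular nuclei (eccentricity < 0.05) receive the
#' tie-break orientation 0 degrees and are flagged undefined so they can be
#' excluded from orientation statistics.
#'
#' @param mask `nm_nuclear_mask` or integer label matrix.
#' @param image `nm_spot_image` or height x width x 3 array matching the
#'   mask dimensions.
#' @return list of `nm_nucleus` records: `label`, `centroid` (x, y in
#'   pixels), `boundary` (two-column polygon), `area` (px^2), `perimeter`
#'   (px), `orientation` (degrees), `eccentricity`,
#'   `orientation_defined`, `per_channel_pixels` (list R/G/B),
#'   `patch` (bounding-box intensity patches + interior logical).
#'   Degenerate labels (< 5 px or boundary shorter than 8 vertices after
#'   tracing) are dropped with a message.
#' @export
extract_nucleus_records <- function(mask, image) {
  labels <- get_mask_labels(mask)
  px <- if (inherits(image, "nm_spot_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3,
            dim(px)[1] == nrow(labels), dim(px)[2] == ncol(labels))
  ids <- sort(unique(labels[labels > 0]))
  records <- list()
  dropped <- 0L
  for (k in ids) {
    sel <- which(labels == k, arr.ind = TRUE)
    if (nrow(sel) < 5) { dropped <- dropped + 1L; next }
    rows <- sel[, 1]; cols <- sel[, 2]
    cx <- mean(cols); cy <- mean(rows)
    # central second moments in the y-up frame
    dx <- cols - cx; dy <- -(rows - cy)
    mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
    common <- sqrt(4 * mu11^2 + (mu20 - mu02)^2)
    l1 <- (mu20 + mu02 + common) / 2
    l2 <- (mu20 + mu02 - common) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))
    theta <- (0.5 * atan2(2 * mu11, mu20 - mu02)) * 180 / pi
    theta <- theta %% 180
    defined <- ecc >= 0.05
    if (!defined) theta <- 0
    bnd <- object_contour(labels, k)
    if (nrow(bnd) < 8) { dropped <- dropped + 1L; next }
    per <- polygon_perimeter(bnd)
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    interior <- labels[r0:r1, c0:c1, drop = FALSE] == k
    patch <- lapply(1:3, function(ch) px[r0:r1, c0:c1, ch, drop = TRUE])
    records[[length(records) + 1L]] <- structure(list(
      label = k,
      centroid = c(x = cx, y = cy),
      boundary = bnd,
      area = nrow(sel),
      perimeter = per,
      orientation = theta,
      eccentricity = ecc,
      orientation_defined = defined,
      per_channel_pixels = lapply(1:3, function(ch)
        px[cbind(rows, cols, ch)]),
      patch = list(channels = patch, interior = interior)),
      class = "nm_nucleus")
  }
  if (dropped > 0)
    message(dropped, " degenerate label(s) dropped during record extraction")
  attr(records, "n_dropped") <- dropped
  records
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
}

#' Write per-nucleus records to CSV
#' @param records list of `nm_nucleus`.
#' @param path CSV path.
#' @return path, invisibly.
#' @export
write_nucleus_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(label = r$label, x = r$centroid["x"], y = r$centroid["y"],
               area = r$area, perimeter = r$perimeter,
               orientation = r$orientation, eccentricity = r$eccentricity)))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
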