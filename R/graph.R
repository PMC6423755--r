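# Bounded coefficient-of-variation transform used to aggregate graph
# attributes: 0 <= disorder < 1, with disorder = 0 iff SD = 0.
disorder_stat <- function(v) {
  if (length(v) < 2) return(0)
  s <- stats::sd(v); m <- mean(v)
  if (s == 0) return(0)
  if (m == 0) return(1 - 1 / (1 + s / .Machine$double.eps))
  1 - 1 / (1 + s / abs(m))
}

graph_aggregate <- function(v) {
  s <- if (length(v) < 2) 0 else stats::sd(v)
  c(average = mean(v), sd = s, minmax_ratio = ratio_minmax(v),
    disorder = disorder_stat(v))
}

check_noncollinear <- function(p, need) {
  if (nrow(p) < need)
    stop("need at least ", need, " centroids, got ", nrow(p))
  cc <- sweep(p, 2, colMeans(p))
  if (svd(cc)$d[2] < 1e-9)
    stop("all centroids are collinear: tessellation undefined")
}

# Farthest intersection of the ray v + t*(c - v), t > 0, with the polygon
# boundary; returns the chord length |v - exit|.
ray_exit_length <- function(v, cen, poly) {
  d <- cen - v
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) return(0)
  q <- rbind(poly, poly[1, , drop = FALSE])
  tmax <- 0
  for (i in seq_len(nrow(poly))) {
    e1 <- q[i, ]; e2 <- q[i + 1, ]
    ex <- e2 - e1
    den <- d[1] * (-ex[2]) - d[2] * (-ex[1])
    if (abs(den) < 1e-12) next
    rhs <- e1 - v
    tt <- (rhs[1] * (-ex[2]) - rhs[2] * (-ex[1])) / den
    ss <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (ss >= -1e-9 && ss <= 1 + 1e-9 && tt > 1e-9) tmax <- max(tmax, tt)
  }
  tmax * nd
}

#' Voronoi-diagram architecture features (12 values)
#'
#' Voronoi tessellation of the nuclear centroids, clipped to the spot
#' bounding box (boundary cells are clipped, not discarded). Per cell the
#' perimeter, the mean vertex-through-centroid chord length, and the area
#' are computed; each attribute is aggregated by average, SD, min/max ratio
#' and disorder, where disorder = 1 - 1/(1 + SD/mean).
#'
#' @param centroids two-column matrix of (x, y) positions (>= 4,
#'   non-collinear).
#' @param bbox clipping window `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   centroid bounding box (or the image extent via `width`/`height`).
#' @param width,height convenience: sets `bbox = c(0.5, width + 0.5, 0.5,
#'   height + 0.5)`.
#' @return named numeric vector of length 12 (`voronoi:<attr>:<stat>`).
#' @export
voronoi_features <- function(centroids, bbox = NULL,
                             width = NULL, height = NULL) {
  p <- as.matrix(centroids)
  check_noncollinear(p, 4)
  if (is.null(bbox)) {
    bbox <- if (!is.null(width) && !is.null(height))
      c(0.5, width + 0.5, 0.5, height + 0.5)
    else c(range(p[, 1]), range(p[, 2]))
  }
  dd <- deldir::deldir(p[, 1], p[, 2], rw = bbox, round = FALSE,
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  perims <- areas <- chords <- numeric(length(tiles))
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    poly <- cbind(tl$x, tl$y)
    perims[i] <- polygon_perimeter(poly)
    areas[i] <- tl$area
    cen <- c(mean(tl$x), mean(tl$y))
    chords[i] <- mean(vapply(seq_len(nrow(poly)), function(k)
      ray_exit_length(poly[k, ], cen, poly), numeric(1)))
  }
  vals <- cbind(perimeter = perims, chord = chords, area = areas)
  m <- vapply(colnames(vals), function(a) graph_aggregate(vals[, a]),
              numeric(4))               # 4 stats x 3 attrs
  out <- as.vector(t(m))                # attr fastest within each stat
  stats::setNames(out, voronoi_feature_names())
}

#' Delaunay-triangulation architecture features (8 values)
#'
#' Delaunay triangulation of the centroids; all edge lengths and triangle
#' areas are collected and each aggregated by mean, SD, min/max ratio and
#' disorder.
#'
#' @param centroids two-column matrix of (x, y) positions (>= 3,
#'   non-collinear).
#' @return named numeric vector of length 8 (`delaunay:<attr>:<stat>`).
#' @export
delaunay_features <- function(centroids) {
  p <- as.matrix(centroids)
  check_noncollinear(p, 3)
  rw <- c(range(p[, 1]) + c(-1, 1), range(p[, 2]) + c(-1, 1))
  dd <- deldir::deldir(p[, 1], p[, 2], rw = rw, round = FALSE,
                       suppressMsge = TRUE)
  e <- dd$delsgs
  lens <- sqrt((e$x1 - e$x2)^2 + (e$y1 - e$y2)^2)
  tris <- deldir::triang.list(dd)
  areas <- vapply(tris, function(tr) polygon_area(cbind(tr$x, tr$y)),
                  numeric(1))
  m <- cbind(side_length = graph_aggregate(lens),
             triangle_area = graph_aggregate(areas))  # 4 stats x 2 attrs
  out <- as.vector(t(m))                # attr fastest within each stat
  names(out) <- delaunay_feature_names()
  # delaunay names use "mean" for the first statistic
  out
}
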