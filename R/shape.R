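# Polygon geometry helpers ---------------------------------------------------

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Exact polygon raw moments M_pq (p + q <= 3) by Green's theorem
# (Steger's closed form). Vertices counterclockwise give positive area;
# sign is normalized away by the caller.
polygon_moment <- function(p, pp, qq) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  s <- 0
  for (k in 0:pp) for (l in 0:qq) {
    coef <- choose(k + l, l) * choose(pp + qq - k - l, qq - l)
    s <- s + coef * sum(cross * x^k * x2^(pp - k) * y^l * y2^(qq - l))
  }
  s / ((pp + qq + 2) * (pp + qq + 1) * choose(pp + qq, pp))
}

# Central moments mu_pq of the filled polygon, p + q <= 3
polygon_central_moments <- function(p) {
  m00 <- polygon_moment(p, 0, 0)
  if (abs(m00) < 1e-12) stop("degenerate polygon: zero area")
  cx <- polygon_moment(p, 1, 0) / m00
  cy <- polygon_moment(p, 0, 1) / m00
  q <- cbind(p[, 1] - cx, p[, 2] - cy)
  mu <- list()
  for (pp in 0:3) for (qq in 0:(3 - pp))
    mu[[paste0("mu", pp, qq)]] <- polygon_moment(q, pp, qq)
  sgn <- sign(mu$mu00)
  lapply(mu, function(v) v * sgn)   # orientation-independent
}

# The seven rotation/translation/scale-invariant algebraic (Hu) moments of
# the filled polygon.
polygon_hu_moments <- function(p) {
  mu <- polygon_central_moments(p)
  m00 <- mu$mu00
  eta <- function(pp, qq) mu[[paste0("mu", pp, qq)]] /
    m00^(1 + (pp + qq) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Resample a closed polygon at n points equally spaced in arc length
resample_polygon <- function(p, n = 128L) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx >= length(cum)] <- length(cum) - 1
  frac <- (target - cum[idx]) / pmax(seg[idx], 1e-12)
  cbind(q[idx, 1] + frac * (q[idx + 1, 1] - q[idx, 1]),
        q[idx, 2] + frac * (q[idx + 1, 2] - q[idx, 2]))
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

# Minimum enclosing circle by brute force over convex-hull vertex pairs and
# triples (hulls here are small).
min_enclosing_circle <- function(p) {
  h <- p[unique(grDevices::chull(p[, 1], p[, 2])), , drop = FALSE]
  n <- nrow(h)
  if (n == 1) return(c(h[1, ], 0))
  tol <- 1e-9
  inside <- function(cc) all((h[, 1] - cc[1])^2 + (h[, 2] - cc[2])^2 <=
                               (cc[3] * (1 + tol))^2 + tol)
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cc <- c((h[i, 1] + h[j, 1]) / 2, (h[i, 2] + h[j, 2]) / 2,
            sqrt(sum((h[i, ] - h[j, ])^2)) / 2)
    if (inside(cc) && (is.null(best) || cc[3] < best[3])) best <- cc
  }
  if (n >= 3)
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      cc <- circumcircle(h[i, ], h[j, ], h[k, ])
      if (!is.null(cc) && inside(cc) &&
          (is.null(best) || cc[3] < best[3])) best <- cc
    }
  best
}

# Box-counting dimension of a boundary curve, clamped to [1, 2]
boundary_fractal_dimension <- function(p, n_dense = 2048L, n_scales = 6L) {
  q <- resample_polygon(p, n_dense)
  l <- max(max(q[, 1]) - min(q[, 1]), max(q[, 2]) - min(q[, 2]))
  if (l <= 0) return(1)
  x0 <- min(q[, 1]); y0 <- min(q[, 2])
  counts <- sizes <- numeric(n_scales)
  for (j in seq_len(n_scales)) {
    s <- l / 2^(j + 1)
    bx <- floor((q[, 1] - x0) / s); by <- floor((q[, 2] - y0) / s)
    counts[j] <- length(unique(bx + 1i * by))
    sizes[j] <- s
  }
  d <- -stats::coef(stats::lm(log(counts) ~ log(sizes)))[2]
  min(max(unname(d), 1), 2)
}

# Shape descriptors -----------------------------------------------------------

#' Per-nucleus shape descriptor set (25 values)
#'
#' Computes the centroid-distance signature `r(t)` of the boundary sampled
#' at `n_points` equal-arc-length positions and derives:
#' distance ratio `max(r)/min(r)`, SD and variance of `r`,
#' min-distance/mean-distance ratio, area ratio (polygon area over minimum
#' enclosing circle area), perimeter ratio (perimeter over convex-hull
#' perimeter), smoothness (mean absolute deviation of `r(t)` from the
#' midpoint of its neighbors), box-counting fractal dimension of the
#' boundary, the seven rotation/translation/scale-invariant algebraic
#' moments of the filled region, and the magnitudes of harmonics 1-10 of
#' the discrete Fourier transform of `r` normalized by harmonic 0.
#'
#' @param x an `nm_nucleus` record or a two-column boundary polygon
#'   (>= 8 vertices, simple).
#' @param n_points boundary resampling count (default 128).
#' @return named numeric vector of length 25 (see
#'   `shape_descriptor_names()`); fractal dimension lies in `[1, 2]`,
#'   smoothness is >= 0.
#' @export
shape_descriptors <- function(x, n_points = 128L) {
  p <- if (inherits(x, "nm_nucleus")) x$boundary else as.matrix(x)
  stopifnot(ncol(p) == 2)
  if (nrow(p) < 8) stop("boundary polygon needs >= 8 vertices")
  a <- polygon_area(p)
  if (a <= 0) stop("degenerate polygon: zero area")

  m00 <- polygon_moment(p, 0, 0)
  cx <- polygon_moment(p, 1, 0) / m00
  cy <- polygon_moment(p, 0, 1) / m00
  q <- resample_polygon(p, n_points)
  r <- sqrt((q[, 1] - cx)^2 + (q[, 2] - cy)^2)

  mec <- min_enclosing_circle(p)
  hull <- p[unique(grDevices::chull(p[, 1], p[, 2])), , drop = FALSE]
  r_prev <- c(r[length(r)], r[-length(r)])
  r_next <- c(r[-1], r[1])
  fr <- abs(stats::fft(r))
  fd <- fr[2:11] / fr[1]

  out <- c(
    area_ratio = a / (pi * mec[3]^2),
    distance_ratio = max(r) / min(r),
    sd_of_distance = stats::sd(r),
    min_mean_distance_ratio = min(r) / mean(r),
    perimeter_ratio = polygon_perimeter(p) / polygon_perimeter(hull),
    variance_of_distance = stats::var(r),
    fractal_dimension = boundary_fractal_dimension(p),
    smoothness = mean(abs(r - (r_prev + r_next) / 2)),
    stats::setNames(polygon_hu_moments(p), paste0("invariant_moment_", 1:7)),
    stats::setNames(fd, paste0("fourier_descriptor_", 1:10)))
  names(out) <- shape_descriptor_names()
  out
}

ratio_minmax <- function(v) {
  mx <- max(v); mn <- min(v)
  if (mx == mn) return(1)
  if (mx == 0) return(0)
  mn / mx
}

#' Spot-level shape aggregates (100 values)
#'
#' Aggregates each of the 25 per-nucleus shape descriptors across the
#' spot's nuclei by mean, SD, median and min/max ratio.
#'
#' @param descriptors list of [shape_descriptors()] outputs (>= 2 nuclei).
#' @return named numeric vector of length 100 (`shape:<descriptor>:<stat>`).
#' @export
aggregate_shape <- function(descriptors) {
  if (length(descriptors) < 2)
    stop("insufficient nuclei for aggregation (need >= 2)")
  m <- do.call(rbind, descriptors)         # nuclei x 25
  stopifnot(ncol(m) == 25)
  out <- numeric(0)
  for (d in colnames(m)) {
    v <- m[, d]
    out <- c(out, mean(v), stats::sd(v), stats::median(v), ratio_minmax(v))
  }
  stats::setNames(out, shape_feature_names())
}
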