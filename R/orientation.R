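# The 13 Haralick-family descriptors of a normalized, symmetric
# co-occurrence matrix P (logs base 2; degenerate marginals give 0 for
# correlation and the information measures).
cooccurrence_descriptors <- function(P) {
  B <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  pos <- P > 0
  ent2 <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }

  # |i - j| and i + j marginal distributions
  pxmy <- vapply(0:(B - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kd <- 0:(B - 1)
  pxpy <- vapply(2:(2 * B), function(k) sum(P[(i + j) == k]), numeric(1))
  ks <- 2:(2 * B)

  ca <- sum(kd * pxmy)
  ia <- sum(ks * pxpy)
  H <- ent2(P[pos])
  mux <- sum((1:B) * px); muy <- sum((1:B) * py)
  sdx <- sqrt(sum((1:B)^2 * px) - mux^2)
  sdy <- sqrt(sum((1:B)^2 * py) - muy^2)
  corr <- if (sdx > 1e-12 && sdy > 1e-12)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0

  hx <- ent2(px); hy <- ent2(py)
  ppij <- outer(px, py)
  okj <- pos & ppij > 0
  hxy1 <- -sum(P[okj] * log2(ppij[okj]))
  pp <- ppij[ppij > 0]
  hxy2 <- -sum(pp * log2(pp))
  im1 <- if (max(hx, hy) > 1e-12) (H - hxy1) / max(hx, hy) else 0
  im2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - H))))

  c(contrast_energy = sum(P * (i - j)^2),
    contrast_inverse_moment = sum(P / (1 + (i - j)^2)),
    contrast_average = ca,
    contrast_variance = sum((kd - ca)^2 * pxmy),
    contrast_entropy = ent2(pxmy),
    intensity_average = ia,
    intensity_variance = sum((ks - ia)^2 * pxpy),
    intensity_entropy = ent2(pxpy),
    entropy = H,
    energy = sum(P^2),
    correlation = corr,
    info_measure_1 = im1,
    info_measure_2 = im2)
}

# Per-nucleus orientation co-occurrence matrix over its k nearest
# neighbors: B x B counts of (own bin, neighbor bin), symmetrized and
# normalized to sum 1.
orientation_cooccurrence <- function(bins, neighbors, i, B) {
  M <- matrix(0, B, B)
  for (j in neighbors) M[bins[i], bins[j]] <- M[bins[i], bins[j]] + 1
  M <- (M + t(M)) / 2
  M / sum(M)
}

#' Cell-orientation-graph disorder features (39 values)
#'
#' Quantizes each nucleus's major-axis orientation into `b_bins` equal bins
#' over `[0, 180)` degrees; for each nucleus builds the co-occurrence
#' matrix of (own bin, neighbor bin) over its `k_neighbors` nearest
#' neighbors (by centroid distance), symmetrized and normalized; computes
#' 13 Haralick-family descriptors per nucleus; and aggregates each
#' descriptor across nuclei by mean, SD and range, giving 39 values.
#' Perfectly aligned tissue concentrates all co-occurrence mass in one
#' cell: entropy 0, energy 1, zero SD and range.
#'
#' Nuclei with undefined orientation (near-circular) are excluded; if they
#' are the majority a warning is emitted and the defined subset is used.
#'
#' @param records list of `nm_nucleus`, or a data.frame/list with numeric
#'   `x`, `y`, `orientation` (degrees) and optional logical
#'   `orientation_defined`.
#' @param k_neighbors neighborhood size (default 5).
#' @param b_bins orientation bin count over `[0, 180)` (default 18, 10
#'   degrees per bin).
#' @return named numeric vector of length 39 (`orient:<descriptor>:<stat>`).
#' @export
orientation_features <- function(records, k_neighbors = 5L, b_bins = 18L) {
  if (length(records) && inherits(records[[1]], "nm_nucleus")) {
    xy <- t(vapply(records, function(r) r$centroid, numeric(2)))
    ang <- vapply(records, function(r) r$orientation, numeric(1))
    def <- vapply(records, function(r) r$orientation_defined, logical(1))
  } else {
    df <- as.data.frame(records)
    xy <- cbind(df$x, df$y)
    ang <- df$orientation
    def <- if (!is.null(df$orientation_defined)) df$orientation_defined
           else rep(TRUE, nrow(df))
  }
  if (mean(def) < 0.5)
    warning("fewer than 50% of nuclei have a defined orientation; ",
            "computing on the defined subset")
  xy <- xy[def, , drop = FALSE]
  ang <- ang[def]
  n <- length(ang)
  if (n < k_neighbors + 1)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1,
         " nuclei with defined orientation, got ", n)
  bins <- pmin(floor((ang %% 180) / (180 / b_bins)) + 1L, b_bins)
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  per <- matrix(0, n, 13)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k_neighbors)]
    P <- orientation_cooccurrence(bins, nb, i, b_bins)
    per[i, ] <- cooccurrence_descriptors(P)
  }
  colnames(per) <- orientation_descriptor_names()
  out <- numeric(0)
  for (d in colnames(per)) {
    v <- per[, d]
    out <- c(out, mean(v), stats::sd(v), max(v) - min(v))
  }
  stats::setNames(out, orientation_feature_names())
}
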