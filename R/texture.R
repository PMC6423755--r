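# Gray-level co-occurrence matrix over a masked patch: `levels` gray bins
# scaled to the patch's own intensity range, unit distance, the four
# standard directions averaged, symmetric, normalized to sum 1.
glcm_matrix <- function(patch, interior, levels = 8L, distance = 1L) {
  v <- patch[interior]
  rng <- range(v)
  g <- matrix(NA_integer_, nrow(patch), ncol(patch))
  if (rng[2] > rng[1]) {
    q <- pmin(floor((patch - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
              levels)
  } else q <- matrix(1L, nrow(patch), ncol(patch))
  g[interior] <- q[interior]
  P <- matrix(0, levels, levels)
  offs <- list(c(0, distance), c(distance, 0),
               c(distance, distance), c(distance, -distance))
  nr <- nrow(g); nc <- ncol(g)
  for (o in offs) {
    r1 <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok))
      P <- P + table(factor(a[ok], levels = 1:levels),
                     factor(b[ok], levels = 1:levels))
  }
  P <- P + t(P)                      # symmetrize
  s <- sum(P)
  if (s == 0) return(NULL)
  matrix(P / s, levels, levels)
}

glcm_descriptors <- function(P) {
  lv <- nrow(P)
  i <- row(P); j <- col(P)
  pos <- P > 0
  off <- i != j
  c(contrast = sum(P * (i - j)^2),
    energy = sum(P^2),
    entropy = -sum(P[pos] * log2(P[pos])),
    inverse_variance = if (any(off)) sum(P[off] / (i[off] - j[off])^2) else 0)
}

# First algebraic invariant moment of an intensity patch (intensity-weighted
# second-order central moments, scale-normalized).
patch_invariant_moment <- function(patch, interior) {
  w <- patch
  w[!interior] <- 0
  m00 <- sum(w)
  if (m00 <= 0) return(0)
  xs <- col(w); ys <- row(w)
  cx <- sum(w * xs) / m00; cy <- sum(w * ys) / m00
  mu20 <- sum(w * (xs - cx)^2); mu02 <- sum(w * (ys - cy)^2)
  (mu20 + mu02) / m00^2
}

#' Spot-level nuclear texture features (30 values)
#'
#' For each nucleus and each RGB channel, a gray-level co-occurrence matrix
#' (8 levels, distance 1, symmetric, direction-averaged) over the nuclear
#' interior yields contrast, energy, entropy and inverse variance; the
#' fifth descriptor is the first algebraic invariant moment of the
#' intensity patch. Each descriptor is aggregated across nuclei by mean and
#' SD per channel, giving exactly 5 x 2 x 3 = 30 values. Uniform-intensity
#' nuclei give contrast 0, energy 1, entropy 0.
#'
#' @param records list of `nm_nucleus` from [extract_nucleus_records()].
#' @param image unused (intensities travel inside the records); kept for
#'   call-site symmetry.
#' @param levels gray-level count (default 8).
#' @param distance co-occurrence offset in pixels (default 1).
#' @return named numeric vector of length 30
#'   (`texture:<descriptor>:<channel>:<stat>`).
#' @export
texture_features <- function(records, image = NULL, levels = 8L,
                             distance = 1L) {
  stopifnot(length(records) >= 2)
  skipped <- 0L
  vals <- list()   # vals[[channel]][[descriptor]] = per-nucleus vector
  per <- lapply(records, function(r) {
    interior <- r$patch$interior
    if (sum(interior) < 9) return(NULL)
    chs <- lapply(1:3, function(ch) {
      patch <- r$patch$channels[[ch]]
      P <- glcm_matrix(patch, interior, levels, distance)
      if (is.null(P)) return(NULL)
      c(glcm_descriptors(P),
        invariant_moment = patch_invariant_moment(patch, interior))
    })
    if (any(vapply(chs, is.null, logical(1)))) return(NULL)
    chs
  })
  keep <- !vapply(per, is.null, logical(1))
  skipped <- sum(!keep)
  per <- per[keep]
  if (skipped > 0)
    message(skipped, " nuclei with < 9 interior pixels skipped in texture")
  if (length(per) < 2) stop("fewer than 2 usable nuclei for texture")
  descs <- c("contrast", "energy", "entropy", "inverse_variance",
             "invariant_moment")
  out <- numeric(0)
  for (d in descs) for (ch in 1:3) {
    v <- vapply(per, function(x) unname(x[[ch]][d]), numeric(1))
    out <- c(out, mean(v), stats::sd(v))
  }
  stats::setNames(out, texture_feature_names())
}
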