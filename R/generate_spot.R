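# Published H&E optical-density stain vectors (unit length), rows = stains.
# Residual is the unit vector orthogonal to both.
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, eosin = e, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

# Axial von Mises sampler: draws major-axis angles in [0, 180) degrees with
# mode mu and concentration kappa (kappa = 0 -> uniform). Uses the
# Best-Fisher (1979) rejection sampler on the doubled angle.
rvonmises_axial <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 180))
  if (kappa > 1e6) kappa <- 1e6
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  # th is the doubled angle around 0; fold back to the axial scale
  (mu_deg + th * 90 / pi) %% 180
}

# Pixel coordinates (row, col) covered by an ellipse; angle in degrees,
# measured counterclockwise from +x with y pointing up (row decreasing).
ellipse_pixels <- function(cx, cy, a, b, theta_deg, width, height) {
  t <- theta_deg * pi / 180
  ct <- cos(t); st <- sin(t)
  r0 <- max(1L, floor(cy - a)); r1 <- min(height, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(width, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rows <- r0:r1; cols <- c0:c1
  dx <- rep(cols - cx, each = length(rows))
  dy <- rep(-(rows - cy), times = length(cols))   # y up
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(rows, times = length(cols))[keep],
        col = rep(cols, each = length(rows))[keep])
}

#' Generate a synthetic H&E TMA spot image with ground truth
#'
#' Renders elliptical hematoxylin-stained nuclei on an eosin-pink background
#' by composing optical densities on the standard H&E stain basis
#' (Beer-Lambert), with Gaussian-blurred nuclear edges and additive Gaussian
#' stain noise. Overlaps are avoided by rejection sampling up to a retry
#' cap; nuclei that still cannot be placed without overlap are placed
#' overlapping and reported in a warning.
#'
#' @param params an [spot_sim_params()] object.
#' @param max_tries rejection-sampling retry cap per nucleus.
#' @return a list of class `nm_spot_sim`:
#'   \describe{
#'     \item{image}{`nm_spot_image`: `pixels` (height x width x 3 array in
#'       `[0,1]`) and `microns_per_pixel`.}
#'     \item{mask}{integer height x width matrix, 0 = background, k > 0 =
#'       nucleus k; one positive label per nucleus.}
#'     \item{truth}{data.frame with one row per nucleus: label, x (column),
#'       y (row), semi-axes a/b, orientation_deg, eccentricity, area_px.}
#'     \item{n_overlapping}{count of nuclei placed past the retry cap.}
#'   }
#' Rendering is a deterministic function of `params$seed`.
#' @export
generate_spot_image <- function(params, max_tries = 200L) {
  stopifnot(inherits(params, "nm_spot_params"))
  with_local_seed(params$seed, {
    W <- params$width; H <- params$height
    n <- params$n_nuclei

    # nuclear geometry
    cv <- params$area_cv
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      areas <- stats::rlnorm(n, log(params$mean_area) - s2 / 2, sqrt(s2))
    } else areas <- rep(params$mean_area, n)
    areas <- pmax(areas, 16)
    ecc <- stats::runif(n, params$eccentricity_range[1],
                        params$eccentricity_range[2])
    axis_ratio <- sqrt(1 - ecc^2)                       # b / a
    a <- sqrt(areas / (pi * axis_ratio))
    b <- a * axis_ratio
    ang <- rvonmises_axial(n, params$orientation_mu, params$orientation_kappa)

    # cluster parents for inhomogeneous placement
    px <- stats::runif(params$n_clusters, 0.15 * W, 0.85 * W)
    py <- stats::runif(params$n_clusters, 0.15 * H, 0.85 * H)
    csd <- min(W, H) / 12

    mask <- matrix(0L, H, W)
    occupied <- matrix(FALSE, H, W)
    truth <- vector("list", n)
    n_overlap <- 0L
    for (i in seq_len(n)) {
      m <- ceiling(a[i]) + 1
      placed <- FALSE
      pix <- NULL
      for (try in seq_len(max_tries)) {
        if (stats::runif(1) < params$clustering) {
          k <- sample.int(params$n_clusters, 1)
          cx <- stats::rnorm(1, px[k], csd); cy <- stats::rnorm(1, py[k], csd)
          cx <- min(max(cx, m + 1), W - m); cy <- min(max(cy, m + 1), H - m)
        } else {
          cx <- stats::runif(1, m + 1, W - m)
          cy <- stats::runif(1, m + 1, H - m)
        }
        pix <- ellipse_pixels(cx, cy, a[i], b[i], ang[i], W, H)
        if (nrow(pix) && !any(occupied[pix])) { placed <- TRUE; break }
      }
      if (!placed) n_overlap <- n_overlap + 1L
      idx <- cbind(pix[, 1], pix[, 2])
      mask[idx] <- i
      # 2 px separation margin around each placed nucleus
      halo <- ellipse_pixels(cx, cy, a[i] + 2, b[i] + 2, ang[i], W, H)
      occupied[cbind(halo[, 1], halo[, 2])] <- TRUE
      truth[[i]] <- data.frame(label = i, x = cx, y = cy, a = a[i], b = b[i],
                               orientation_deg = ang[i], eccentricity = ecc[i],
                               area_px = nrow(pix))
    }
    if (n_overlap > 0)
      warning(n_overlap, " nuclei placed overlapping after ", max_tries,
              " rejection-sampling tries")

    # render: hematoxylin density inside nuclei, eosin background, soft edges
    dh <- matrix(0, H, W)
    dh[mask > 0] <- 0.85
    dh <- as.matrix(EBImage::gblur(dh, sigma = 1.2))
    de <- matrix(0.25, H, W)
    sm <- he_stain_matrix()
    pixels <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      od <- dh * sm["hematoxylin", ch] + de * sm["eosin", ch]
      img <- 10^(-od)
      if (params$stain_noise_sd > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, params$stain_noise_sd), H, W)
      pixels[, , ch] <- pmin(pmax(img, 0), 1)
    }
    truth <- do.call(rbind, truth)
    structure(list(image = new_spot_image(pixels, params$microns_per_pixel),
                   mask = mask, truth = truth, n_overlapping = n_overlap),
              class = "nm_spot_sim")
  })
}

#' Construct a spot image container
#'
#' @param pixels height x width x 3 numeric array, intensities in `[0, 1]`.
#' @param microns_per_pixel physical pixel size.
#' @return `nm_spot_image` object.
#' @export
new_spot_image <- function(pixels, microns_per_pixel = 0.25) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 64, dim(pixels)[2] >= 64,
            all(pixels >= 0), microns_per_pixel > 0)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "nm_spot_image")
}

#' Write / read spot images and label masks
#'
#' Images are written as 8-bit RGB PNG; masks as 16-bit single-channel TIFF.
#' @param spot an `nm_spot_image`.
#' @param path output file path.
#' @return `write_*` return `path` invisibly; readers return the object.
#' @export
write_spot_image <- function(spot, path) {
  stopifnot(inherits(spot, "nm_spot_image"))
  png::writePNG(spot$pixels, path)
  invisible(path)
}

#' @rdname write_spot_image
#' @param microns_per_pixel pixel size to attach on read.
#' @export
read_spot_image <- function(path, microns_per_pixel = 0.25) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  new_spot_image(px, microns_per_pixel)
}

#' @rdname write_spot_image
#' @param mask integer label matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_spot_image
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
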