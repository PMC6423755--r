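# Canonical feature naming. The 189-feature vector is the ordered
# concatenation shape(100) + texture(30) + orientation(39) + voronoi(12) +
# delaunay(8); names are "<family>:<descriptor>[:<channel>]:<statistic>".
# The per-descriptor name lists are reconstructed from the published family
# counts; the original supplementary name list is not public.

shape_descriptor_names <- function() {
  c("area_ratio", "distance_ratio", "sd_of_distance",
    "min_mean_distance_ratio", "perimeter_ratio", "variance_of_distance",
    "fractal_dimension", "smoothness",
    paste0("invariant_moment_", 1:7),
    paste0("fourier_descriptor_", 1:10))
}

shape_stat_names <- function() c("mean", "sd", "median", "minmax_ratio")

texture_descriptor_names <- function() {
  c("contrast", "energy", "entropy", "inverse_variance", "invariant_moment")
}

orientation_descriptor_names <- function() {
  c("contrast_energy", "contrast_inverse_moment", "contrast_average",
    "contrast_variance", "contrast_entropy", "intensity_average",
    "intensity_variance", "intensity_entropy", "entropy", "energy",
    "correlation", "info_measure_1", "info_measure_2")
}

voronoi_feature_names <- function() {
  as.vector(outer(c("perimeter", "chord", "area"),
                  c("average", "sd", "minmax_ratio", "disorder"),
                  function(a, s) paste("voronoi", a, s, sep = ":")))
}

delaunay_feature_names <- function() {
  as.vector(outer(c("side_length", "triangle_area"),
                  c("mean", "sd", "minmax_ratio", "disorder"),
                  function(a, s) paste("delaunay", a, s, sep = ":")))
}

shape_feature_names <- function() {
  as.vector(vapply(shape_descriptor_names(), function(d)
    paste("shape", d, shape_stat_names(), sep = ":"), character(4)))
}

texture_feature_names <- function() {
  out <- character(0)
  for (d in texture_descriptor_names())
    for (ch in c("R", "G", "B"))
      out <- c(out, paste("texture", d, ch, c("mean", "sd"), sep = ":"))
  out
}

orientation_feature_names <- function() {
  as.vector(vapply(orientation_descriptor_names(), function(d)
    paste("orient", d, c("mean", "sd", "range"), sep = ":"), character(3)))
}

#' Canonical names of the 189 spot features
#'
#' Fixed, documented column order of the quantitative-histomorphometry
#' vector: 100 nuclear-shape aggregates, 30 nuclear-texture aggregates,
#' 39 orientation-disorder co-occurrence aggregates, 12 Voronoi and 8
#' Delaunay architecture aggregates.
#'
#' @return character vector of length 189, unique names.
#' @export
feature_names <- function() {
  c(shape_feature_names(), texture_feature_names(),
    orientation_feature_names(), voronoi_feature_names(),
    delaunay_feature_names())
}

#' Family tag of each of the 189 features
#' @return factor of length 189 with levels shape, texture, orient,
#'   voronoi, delaunay in vector order.
#' @export
feature_families <- function() {
  nm <- feature_names()
  factor(sub(":.*$", "", nm),
         levels = c("shape", "texture", "orient", "voronoi", "delaunay"))
}

#' Assemble the 189-feature spot vector from its five families
#'
#' @param shape named numeric of length 100 ([aggregate_shape()]).
#' @param texture named numeric of length 30 ([texture_features()]).
#' @param orientation named numeric of length 39 ([orientation_features()]).
#' @param voronoi named numeric of length 12 ([voronoi_features()]).
#' @param delaunay named numeric of length 8 ([delaunay_features()]).
#' @param spot_id optional identifier attached as an attribute.
#' @return named numeric vector of length 189 in canonical order, with
#'   attributes `spot_id` and `families`.
#' @export
assemble_feature_vector <- function(shape, texture, orientation,
                                    voronoi, delaunay, spot_id = NA) {
  fams <- list(shape = list(shape, 100L), texture = list(texture, 30L),
               orientation = list(orientation, 39L),
               voronoi = list(voronoi, 12L), delaunay = list(delaunay, 8L))
  for (f in names(fams)) {
    v <- fams[[f]][[1]]; want <- fams[[f]][[2]]
    if (length(v) != want)
      stop("family ", f, " expected ", want, " features, got ", length(v))
  }
  out <- c(shape, texture, orientation, voronoi, delaunay)
  want <- feature_names()
  if (is.null(names(out)) || !identical(names(out), want)) {
    if (!is.null(names(out)) && setequal(names(out), want)) out <- out[want]
    else names(out) <- want
  }
  attr(out, "spot_id") <- spot_id
  attr(out, "families") <- feature_families()
  out
}

#' Extract all 189 features from a segmented spot
#'
#' Convenience wrapper running the shape, texture, orientation, Voronoi and
#' Delaunay extractors on a labeled mask + image pair and assembling the
#' canonical vector.
#'
#' @param mask `nm_nuclear_mask` or integer label matrix.
#' @param image `nm_spot_image`.
#' @param spot_id identifier carried through.
#' @param b_bins,k_neighbors orientation co-occurrence parameters
#'   (see [orientation_features()]).
#' @return named numeric vector of length 189.
#' @export
compute_spot_features <- function(mask, image, spot_id = NA,
                                  b_bins = 18L, k_neighbors = 5L) {
  records <- extract_nucleus_records(mask, image)
  if (length(records) < 4)
    stop("need at least 4 segmented nuclei to compute spot features, got ",
         length(records))
  desc <- lapply(records, shape_descriptors)
  shp <- aggregate_shape(desc)
  tex <- texture_features(records, image)
  ori <- orientation_features(records, k_neighbors = k_neighbors,
                              b_bins = b_bins)
  cen <- t(vapply(records, function(r) r$centroid, numeric(2)))
  vor <- voronoi_features(cen, width = ncol(get_mask_labels(mask)),
                          height = nrow(get_mask_labels(mask)))
  del <- delaunay_features(cen)
  assemble_feature_vector(shp, tex, ori, vor, del, spot_id = spot_id)
}

#' Write / read a one-row-per-spot feature table
#'
#' @param features numeric matrix or data.frame, spots x 189, with canonical
#'   column names, plus a `spot_id` column on write.
#' @param path CSV path.
#' @return the path (write) or a data.frame (read).
#' @export
write_feature_csv <- function(features, path) {
  df <- as.data.frame(features, check.names = FALSE)
  if (!"spot_id" %in% names(df))
    df <- cbind(spot_id = rownames(df) %||% seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
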