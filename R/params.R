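#' Simulation parameters for one synthetic TMA spot
#'
#' Bundles and validates the knobs of the synthetic tissue-microarray spot
#' generator. Nuclei are elliptical, hematoxylin-stained, placed either
#' homogeneously or in clusters, with a controllable common orientation.
#'
#' @param n_nuclei number of nuclei to place (>= 1).
#' @param mean_area mean nuclear area in pixel^2.
#' @param area_cv coefficient of variation of nuclear area (>= 0; lognormal).
#' @param eccentricity_range length-2 numeric in `[0, 1)`; per-nucleus
#'   eccentricity is uniform on this interval.
#' @param orientation_kappa concentration of the axial von Mises orientation
#'   distribution. 0 gives uniformly disordered orientations; large values
#'   align all nuclei to `orientation_mu`.
#' @param orientation_mu preferred major-axis angle, degrees in `[0, 180)`.
#' @param clustering in `[0, 1]`: probability that a nucleus is placed around
#'   a cluster parent rather than uniformly (0 = homogeneous Poisson-like
#'   placement, 1 = fully clustered).
#' @param n_clusters number of cluster parents when `clustering > 0`.
#' @param stain_noise_sd additive Gaussian noise SD on the rendered
#'   intensities (intensity units, image scale `[0, 1]`).
#' @param width,height canvas size in pixels.
#' @param microns_per_pixel physical pixel size (default 0.25 um/px, the
#'   40x scanner resolution the pipeline assumes).
#' @param seed integer seed making the rendering reproducible.
#'
#' @return an object of class `nm_spot_params` (a validated list).
#' @export
spot_sim_params <- function(n_nuclei = 150L,
                            mean_area = 450,
                            area_cv = 0.25,
                            eccentricity_range = c(0.3, 0.7),
                            orientation_kappa = 4,
                            orientation_mu = 90,
                            clustering = 0.2,
                            n_clusters = 6L,
                            stain_noise_sd = 0.03,
                            width = 1024L,
                            height = 1024L,
                            microns_per_pixel = 0.25,
                            seed = 1L) {
  stopifnot(is.numeric(n_nuclei), length(n_nuclei) == 1, n_nuclei >= 1,
            is.numeric(mean_area), mean_area > 0,
            is.numeric(area_cv), area_cv >= 0,
            length(eccentricity_range) == 2,
            all(eccentricity_range >= 0), all(eccentricity_range < 1),
            eccentricity_range[1] <= eccentricity_range[2],
            is.numeric(orientation_kappa), orientation_kappa >= 0,
            orientation_mu >= 0, orientation_mu < 180,
            clustering >= 0, clustering <= 1,
            n_clusters >= 1,
            stain_noise_sd >= 0,
            width >= 64, height >= 64,
            microns_per_pixel > 0)
  if (n_nuclei * mean_area > 0.8 * width * height)
    stop("requested total nucleus area (", n_nuclei * mean_area,
         " px^2) exceeds 80% of the canvas; reduce n_nuclei or mean_area")
  structure(list(n_nuclei = as.integer(n_nuclei), mean_area = mean_area,
                 area_cv = area_cv, eccentricity_range = eccentricity_range,
                 orientation_kappa = orientation_kappa,
                 orientation_mu = orientation_mu,
                 clustering = clustering, n_clusters = as.integer(n_clusters),
                 stain_noise_sd = stain_noise_sd,
                 width = as.integer(width), height = as.integer(height),
                 microns_per_pixel = microns_per_pixel,
                 seed = as.integer(seed)),
            class = "nm_spot_params")
}

#' Simulation parameters for a synthetic patient cohort
#'
#' Defines a cohort in which nuclear disorder drives recurrence risk:
#' recurrence-positive patients receive high-disorder spot parameters (low
#' orientation concentration, high area variability, more clustering) and
#' exponential survival times whose hazard is scaled by `hazard_ratio`.
#'
#' @param n_patients cohort size.
#' @param recurrence_fraction expected fraction of recurrence-positive
#'   patients in (0, 1).
#' @param hazard_ratio multiplicative hazard of the recurrence-positive
#'   (high-disorder) group; must be > 0.
#' @param baseline_hazard events per month in the negative group.
#' @param censor_rate probability of independent uniform censoring in
#'   `[0, 1)`, applied on top of the administrative follow-up cap.
#' @param follow_up_cap administrative censoring time, months (> 0).
#' @param effect_features character vector of feature names whose simulated
#'   distribution is shifted in the positive group (feature-level cohort).
#' @param effect_size standardized mean difference applied to
#'   `effect_features`.
#' @param seed integer seed.
#'
#' @return an object of class `nm_cohort_params`.
#' @export
cohort_sim_params <- function(n_patients = 160L,
                              recurrence_fraction = 0.225,
                              hazard_ratio = 17.24,
                              baseline_hazard = 0.002,
                              censor_rate = 0.10,
                              follow_up_cap = 60,
                              effect_features = default_effect_features(),
                              effect_size = 1.5,
                              seed = 1L) {
  stopifnot(is.numeric(n_patients), n_patients >= 2,
            recurrence_fraction > 0, recurrence_fraction < 1,
            is.numeric(baseline_hazard), baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1,
            is.character(effect_features), length(effect_features) >= 1,
            is.numeric(effect_size))
  if (!is.numeric(hazard_ratio) || length(hazard_ratio) != 1 ||
      hazard_ratio <= 0)
    stop("hazard_ratio must be a positive real")
  if (follow_up_cap <= 0) stop("follow_up_cap must be > 0")
  bad <- setdiff(effect_features, feature_names())
  if (length(bad))
    stop("unknown effect_features: ", paste(bad, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 recurrence_fraction = recurrence_fraction,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 follow_up_cap = follow_up_cap,
                 effect_features = effect_features,
                 effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "nm_cohort_params")
}

#' Default disorder-linked feature names for cohort simulation
#'
#' Five orientation-disorder features, mirroring the dominance of
#' orientation-derived features among the discriminative set.
#' @return character vector of 5 canonical feature names.
#' @export
default_effect_features <- function() {
  c("orient:intensity_entropy:range", "orient:energy:range",
    "orient:intensity_average:sd", "shape:perimeter_ratio:sd",
    "voronoi:perimeter:disorder")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards so generators never perturb a session.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
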